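# Interchange formats.  Internal coordinates are 0-based half-open
# everywhere; conversion to/from the 1-based inclusive on-disk convention
# happens only at the GFF3 boundary.

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings that represent records as a named
#' character vector and round-trip identifiers and sequence content (case
#' included) exactly.
#'
#' @param path file path.
#' @param on_duplicate `"error"` or `"warn"` for duplicate identifiers.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, on_duplicate = c("error", "warn")) {
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  out <- setNames(as.character(x), names(x))
  if (anyDuplicated(names(out))) {
    msg <- paste("duplicate FASTA identifiers:",
                 paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
    if (on_duplicate == "error") stop(msg) else warning(msg)
  }
  out
}

#' @rdname read_fasta
#' @param records named character vector of sequences.
#' @param width line-wrap width (0 for unwrapped).
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    if (width > 0 && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features plus a `SECIS_element`
#' feature per annotated SECIS interval; Sec codon indices are stored in a
#' `sec_codons` attribute of the mRNA.  Coordinates are converted from the
#' internal 0-based half-open convention to GFF3's 1-based inclusive.
#'
#' @param genes a list of [coding_gene()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    span <- range(c(g$exons, g$secis))
    row <- function(type, s, e, attrs)
      sprintf("%s\tselevo\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$seqid, type, s + 1L, e, g$strand, attrs)
    gid <- g$id; mid <- paste0(gid, ".t1")
    lines <- c(lines,
               row("gene", span[1], span[2], paste0("ID=", gid)),
               row("mRNA", span[1], span[2],
                   paste0("ID=", mid, ";Parent=", gid,
                          if (length(g$sec_codons))
                            paste0(";sec_codons=", paste(g$sec_codons, collapse = ","))
                          else "")))
    for (k in seq_len(nrow(g$exons)))
      lines <- c(lines, row("exon", g$exons[k, 1], g$exons[k, 2],
                            paste0("ID=", mid, ".exon", k, ";Parent=", mid)))
    lines <- c(lines, row("CDS", g$cds[1], g$cds[2],
                          paste0("ID=", mid, ".cds;Parent=", mid)))
    for (k in seq_len(nrow(g$secis)))
      lines <- c(lines, row("SECIS_element", g$secis[k, 1], g$secis[k, 2],
                            paste0("ID=", mid, ".secis", k, ";Parent=", mid,
                                   ";core_start=", g$secis_core[k] + 1L)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file (via rtracklayer) into [coding_gene()] objects, one
#' per mRNA, converting coordinates to 0-based half-open.  `SECIS_element`
#' children and a `sec_codons` mRNA attribute are recognized when present.
#'
#' @param path GFF3 file path.
#' @return list of `coding_gene` objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  lapply(seq_len(nrow(mrnas)), function(i) {
    m <- mrnas[i, ]
    kids <- df[!is.na(df$Parent) & df$Parent == m$ID, , drop = FALSE]
    exons <- kids[kids$type == "exon", , drop = FALSE]
    cds <- kids[kids$type == "CDS", , drop = FALSE]
    secis <- kids[kids$type == "SECIS_element", , drop = FALSE]
    if (!nrow(exons)) exons <- cds
    if (!nrow(cds)) stop("mRNA without CDS in ", path, ": ", m$ID)
    sec_codons <- integer()
    if ("sec_codons" %in% names(m) && !is.na(m$sec_codons))
      sec_codons <- as.integer(strsplit(as.character(m$sec_codons), ",")[[1]])
    core <- if (nrow(secis) && "core_start" %in% names(secis) &&
                !anyNA(secis$core_start))
      as.integer(secis$core_start) - 1L else NULL
    coding_gene(id = sub("\\.t[0-9]+$", "", m$ID), seqid = as.character(m$seqnames),
                strand = as.character(m$strand),
                exons = cbind(exons$start - 1L, exons$end),
                cds = c(min(cds$start) - 1L, max(cds$end)),
                sec_codons = sec_codons,
                secis = if (nrow(secis)) cbind(secis$start - 1L, secis$end)
                        else NULL,
                secis_core = core)
  })
}

#' Gene models of a simulated genome
#'
#' Converts the truth table of [simulate_genome()] into [coding_gene()]
#' objects (one single-exon gene per planted model).
#'
#' @param sim result of [simulate_genome()].
#' @param seqid sequence name to record.
#' @return list of `coding_gene` objects.
#' @export
truth_genes <- function(sim, seqid = "sim") {
  tr <- sim$truth
  lapply(seq_len(nrow(tr)), function(i) {
    t1 <- tr[i, ]
    sec_idx <- (t1$sec_start - t1$cds_start) %/% 3L + 1L
    coding_gene(id = t1$gene, seqid = seqid, strand = t1$strand,
                exons = cbind(t1$gene_start, t1$gene_end),
                cds = c(t1$cds_start, t1$cds_end),
                sec_codons = sec_idx,
                secis = cbind(t1$secis_start, t1$secis_end),
                secis_core = t1$core5_start)
  })
}

#' Write SECIS hits as TSV
#' @param hits a `secis_hits` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_secis_hits <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
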