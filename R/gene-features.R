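# Selenoprotein gene geometry.  All genomic intervals are 0-based,
# half-open; every transcript-level measure is computed on the spliced
# (mRNA) sequence, so intron placement never changes a distance.

#' Selenoprotein gene model
#'
#' @param id gene identifier.
#' @param seqid name of the genomic sequence the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (or data.frame) of 0-based half-open
#'   genomic exon intervals.
#' @param cds length-2 vector: genomic begin of the start codon and genomic
#'   end of the stop codon (0-based half-open; the stop codon is part of
#'   the CDS interval).
#' @param sec_codons integer codon indices (1-based within the spliced CDS)
#'   carrying the Sec UGA.
#' @param secis matrix of 0-based half-open genomic SECIS intervals
#'   (0 rows when none annotated).
#' @param secis_core optional genomic positions of the 5' core starts (one
#'   per SECIS interval; defaults to the interval starts).
#' @return an object of class `coding_gene`.
#' @export
coding_gene <- function(id, seqid, strand, exons, cds, sec_codons = integer(),
                        secis = NULL, secis_core = NULL) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons")
  if (!strand %in% c("+", "-")) stop("strand must be + or -")
  cds <- as.integer(cds)
  if (is.null(secis)) secis <- matrix(integer(), 0, 2)
  secis <- matrix(as.integer(secis), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (is.null(secis_core)) secis_core <- secis[, 1]
  g <- structure(list(id = id, seqid = seqid, strand = strand, exons = exons,
                      cds = cds, sec_codons = as.integer(sec_codons),
                      secis = secis, secis_core = as.integer(secis_core)),
                 class = "coding_gene")
  if (is.na(g2t(g, cds[1])) || is.na(g2t(g, cds[2] - 1L)))
    stop("CDS boundaries fall outside the exons (model error)")
  if (cds_length(g) %% 3 != 0) stop("spliced CDS length not divisible by 3")
  g
}

#' @export
print.coding_gene <- function(x, ...) {
  cat(sprintf("coding_gene %s (%s%s): %d exon(s), CDS [%d,%d), %d Sec codon(s), %d SECIS\n",
              x$id, x$seqid, x$strand, nrow(x$exons), x$cds[1], x$cds[2],
              length(x$sec_codons), nrow(x$secis)))
  invisible(x)
}

# Transcript length (spliced).
transcript_length <- function(gene) sum(gene$exons[, 2] - gene$exons[, 1])

# Map a genomic position (0-based) to its spliced transcript coordinate
# (0-based, 5'->3' in transcript orientation); NA if intronic/outside.
g2t <- function(gene, gpos) {
  ex <- gene$exons
  off <- cumsum(c(0L, ex[, 2] - ex[, 1]))
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_len(nrow(ex))) {
    inside <- gpos >= ex[k, 1] & gpos < ex[k, 2]
    out[inside] <- off[k] + (gpos[inside] - ex[k, 1])
  }
  if (gene$strand == "-") out <- transcript_length(gene) - 1L - out
  out
}

# Spliced transcript coordinates of the CDS: start of start codon and the
# position just after the stop codon.
cds_transcript_span <- function(gene) {
  if (gene$strand == "+")
    c(g2t(gene, gene$cds[1]), g2t(gene, gene$cds[2] - 1L) + 1L)
  else
    c(g2t(gene, gene$cds[2] - 1L), g2t(gene, gene$cds[1]) + 1L)
}

cds_length <- function(gene) {
  sp <- cds_transcript_span(gene)
  sp[2] - sp[1]
}

#' UTR lengths of a gene model
#'
#' Spliced-transcript nucleotide counts upstream of the start codon and
#' downstream of the stop codon (the stop codon itself belongs to the CDS,
#' not the 3'-UTR).
#'
#' @param gene a [coding_gene()].
#' @return named numeric vector `c(utr5_len, utr3_len)`.
#' @export
utr_lengths <- function(gene) {
  sp <- cds_transcript_span(gene)
  c(utr5_len = sp[1], utr3_len = transcript_length(gene) - sp[2])
}

# Transcript coordinate of each SECIS 5'-core start.
secis_core_t <- function(gene) {
  if (!nrow(gene$secis)) return(integer())
  ct <- g2t(gene, gene$secis_core)
  if (anyNA(ct)) stop("SECIS core falls outside the exons")
  ct
}

#' UGA-to-SECIS distances
#'
#' For each Sec codon, the number of spliced-mRNA nucleotides strictly
#' between the UGA codon and the 5' core start of the nearest downstream
#' SECIS element.  Distances below `min_spacing` are flagged: spacings under
#' the experimentally defined minimum (51-111 nt) are unlikely to support
#' Sec insertion.
#'
#' @param gene a [coding_gene()] with at least one Sec codon and one SECIS.
#' @param min_spacing flag threshold in nt.
#' @return data.frame with `sec_codon`, `distance`, `below_min`.
#' @export
uga_to_secis_distance <- function(gene, min_spacing = 111L) {
  if (!length(gene$sec_codons)) stop("gene has no Sec codons")
  if (!nrow(gene$secis)) stop("gene has no SECIS intervals")
  sp <- cds_transcript_span(gene)
  core_t <- sort(secis_core_t(gene))
  res <- lapply(gene$sec_codons, function(i) {
    uga_end <- sp[1] + 3L * i        # transcript pos after the UGA codon
    down <- core_t[core_t >= uga_end]
    if (!length(down))
      stop("SECIS upstream of the UGA in mRNA coordinates (orientation error)")
    d <- down[1] - uga_end
    data.frame(sec_codon = i, distance = d, below_min = d < min_spacing)
  })
  do.call(rbind, res)
}

#' Stop-codon-to-SECIS distance
#'
#' Spliced-mRNA nucleotides strictly between the stop codon and the 5' core
#' start of the first downstream SECIS element.
#'
#' @param gene a [coding_gene()] with at least one SECIS.
#' @return integer distance.
#' @export
stop_to_secis_distance <- function(gene) {
  if (!nrow(gene$secis)) stop("gene has no SECIS intervals")
  sp <- cds_transcript_span(gene)
  core_t <- sort(secis_core_t(gene))
  down <- core_t[core_t >= sp[2]]
  if (!length(down)) stop("SECIS upstream of the stop codon (orientation error)")
  down[1] - sp[2]
}

# Spliced transcript sequence of a gene on a genome sequence.
spliced_sequence <- function(gene, genome_sequence) {
  seq <- toupper(genome_sequence)
  parts <- apply(gene$exons, 1, function(e) substr(seq, e[1] + 1L, e[2]))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
        collapse = "")
}

#' Readthrough extension past the primary stop codon
#'
#' Translation continued past the annotated stop codon to the next in-frame
#' stop in the spliced transcript.  Intervening in-frame UGA codons are
#' rendered as the Sec symbol `U` and do not terminate the extension; TAA
#' and TAG do.
#'
#' @param gene a [coding_gene()].
#' @param genome_sequence the genomic sequence of `gene$seqid`.
#' @return list with `ext_nt` (nucleotides between the primary stop and the
#'   next in-frame stop), `ext_residues` (translated extension), and
#'   `open_ended` (`TRUE` when no in-frame stop occurs before the
#'   transcript end, in which case `ext_nt` is `NA`).
#' @export
readthrough_extension <- function(gene, genome_sequence) {
  tx <- spliced_sequence(gene, genome_sequence)
  sp <- cds_transcript_span(gene)
  pos <- sp[2]                       # 0-based, just after the stop codon
  residues <- character()
  while (pos + 3L <= nchar(tx)) {
    codon <- substr(tx, pos + 1L, pos + 3L)
    if (codon %in% c("TAA", "TAG"))
      return(list(ext_nt = pos - sp[2],
                  ext_residues = paste(residues, collapse = ""),
                  open_ended = FALSE))
    residues <- c(residues, if (codon == "TGA") "U" else codon_aa(codon))
    pos <- pos + 3L
  }
  list(ext_nt = NA_integer_, ext_residues = paste(residues, collapse = ""),
       open_ended = TRUE)
}

#' Classify the codon at a Sec site
#'
#' In selenoprotein context TGA is the Sec codon; TGT/TGC encode Cys;
#' TAA/TAG are stops; every other codon is reported as
#' `other(<residue>)` using the standard genetic code.
#'
#' @param codon 3-base codon string over ACGT (vectorized).
#' @return character vector of classifications.
#' @export
classify_sec_site <- function(codon) {
  codon <- toupper(codon)
  if (any(!grepl("^[ACGT]{3}$", codon)))
    stop("codon must be 3 bases over ACGT")
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val")
  vapply(codon, function(cod) {
    if (cod == "TGA") return("sec")
    if (cod %in% c("TGT", "TGC")) return("cys")
    if (cod %in% c("TAA", "TAG")) return("stop")
    paste0("other(", aa3[[codon_aa(cod)]], ")")
  }, character(1), USE.NAMES = FALSE)
}

#' Detect pseudogene lesions against a reference CDS
#'
#' Globally aligns a candidate sequence to an intact reference CDS (affine
#' gaps) and reports lesions: `frameshift` (indel length not divisible
#' by 3), `triplet_deletion`/`triplet_insertion` (frame-preserving indels),
#' and `premature_stop` (a stop codon in the candidate's reading frame
#' before the reference stop; a TGA aligned to a reference TGA is the Sec
#' codon, not a lesion).  Positions are reference codon indices for stops
#' and reference nucleotide offsets for indels.
#'
#' @param candidate_cds candidate nucleotide sequence.
#' @param reference_cds intact reference CDS (length divisible by 3).
#' @param min_coverage minimum fraction of the reference that must align.
#' @return data.frame with columns `type`, `position`, `length` (0 rows for
#'   an intact candidate).
#' @export
detect_pseudogene_lesions <- function(candidate_cds, reference_cds,
                                      min_coverage = 0.5) {
  cand <- toupper(candidate_cds); ref <- toupper(reference_cds)
  if (nchar(ref) %% 3 != 0) stop("reference CDS length not divisible by 3")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cand), Biostrings::DNAString(ref),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -2),
    gapOpening = 8, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  aligned_cols <- ap != "-" & as_ != "-"
  coverage <- sum(aligned_cols) / nchar(ref)
  if (coverage < min_coverage)
    stop(sprintf("alignment covers only %.0f%% of the reference (insufficient homology)",
                 100 * coverage))
  lesions <- list()
  add <- function(type, position, len = 0L)
    lesions[[length(lesions) + 1L]] <<- data.frame(type = type,
                                                   position = position,
                                                   length = len)
  # Indels: runs of gap columns.
  gapcand <- as_ != "-" & ap == "-"   # deletion in candidate
  gapref <- ap != "-" & as_ == "-"    # insertion in candidate
  refpos <- cumsum(as_ != "-")        # reference nt index per column
  runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  for (r in seq_len(nrow(runs(gapcand)))) {
    rr <- runs(gapcand)[r, , drop = FALSE]
    len <- rr[2] - rr[1] + 1L
    add(if (len %% 3 == 0) "triplet_deletion" else "frameshift",
        refpos[rr[1]], -len)
  }
  for (r in seq_len(nrow(runs(gapref)))) {
    rr <- runs(gapref)[r, , drop = FALSE]
    len <- rr[2] - rr[1] + 1L
    add(if (len %% 3 == 0) "triplet_insertion" else "frameshift",
        if (rr[1] > 1) refpos[rr[1] - 1] else 0L, len)
  }
  # Premature stops: candidate codons in the candidate's own frame.
  candpos <- cumsum(ap != "-")
  ncand <- sum(ap != "-")
  cand_nogap <- paste(ap[ap != "-"], collapse = "")
  ref_of_cand <- rep(NA_integer_, ncand)
  ref_of_cand[candpos[aligned_cols]] <- refpos[aligned_cols]
  n_codons <- ncand %/% 3L
  for (ci in seq_len(max(0, n_codons - 1L))) {    # exclude terminal codon
    codon <- substr(cand_nogap, 3L * ci - 2L, 3L * ci)
    if (!codon %in% c("TAA", "TAG", "TGA")) next
    rp <- ref_of_cand[3L * ci - 2L]
    ref_codon_idx <- if (is.na(rp)) NA_integer_ else (rp - 1L) %/% 3L + 1L
    if (codon == "TGA" && !is.na(ref_codon_idx)) {
      ref_codon <- substr(ref, 3L * ref_codon_idx - 2L, 3L * ref_codon_idx)
      if (ref_codon == "TGA") next   # the Sec codon itself
    }
    add("premature_stop", ref_codon_idx)
  }
  if (!length(lesions))
    return(data.frame(type = character(), position = integer(),
                      length = integer()))
  out <- do.call(rbind, lesions)
  out[order(out$position), , drop = FALSE]
}

#' Gene feature summary
#'
#' Computes the full geometry record of a selenoprotein gene model: UTR
#' lengths, per-Sec-codon UGA-to-SECIS distances, stop-to-SECIS distance,
#' number of SECIS elements, and (when the genomic sequence is supplied)
#' the readthrough extension past the stop codon.
#'
#' @param gene a [coding_gene()].
#' @param genome_sequence optional genomic sequence for the readthrough
#'   measurement.
#' @return list of class `gene_features`.
#' @export
gene_features <- function(gene, genome_sequence = NULL) {
  u <- utr_lengths(gene)
  has_secis <- nrow(gene$secis) > 0
  uga <- if (has_secis && length(gene$sec_codons))
    uga_to_secis_distance(gene) else NULL
  out <- list(id = gene$id,
              utr5_len = unname(u["utr5_len"]),
              utr3_len = unname(u["utr3_len"]),
              n_secis = nrow(gene$secis),
              uga_to_secis = uga,
              stop_to_secis = if (has_secis) stop_to_secis_distance(gene) else NA,
              readthrough = if (!is.null(genome_sequence))
                readthrough_extension(gene, genome_sequence) else NULL)
  class(out) <- "gene_features"
  out
}

#' @export
print.gene_features <- function(x, ...) {
  cat(sprintf("gene %s: 5'UTR %d nt, 3'UTR %d nt, %d SECIS, stop-to-SECIS %s\n",
              x$id, x$utr5_len, x$utr3_len, x$n_secis,
              ifelse(is.na(x$stop_to_secis), "NA", x$stop_to_secis)))
  if (!is.null(x$uga_to_secis)) print(x$uga_to_secis)
  invisible(x)
}
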