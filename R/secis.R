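# SECIS element detection with an explicit structural grammar.  The scanned
# geometry, 5'->3' (all coordinates 0-based, half-open):
#
#   [helix1 5' arm][5' core ATGA][helix2 5' arm][apical loop][helix2 3' arm][GA][helix1 3' arm]
#
# The core quartet (AUGA/GA, non-Watson-Crick) is required verbatim; helix 2
# must pair within a mismatch allowance (G.U counts as canonical); helix 1 --
# the stem closing the quartet from below -- must pair exactly.  The two
# functionally important unpaired bases sit at a fixed offset inside the
# apical loop.  Matching is pure index geometry plus complementarity; no
# thermodynamic folding.

#' SECIS grammar parameters
#'
#' @param core_5p 5' core motif (IUPAC; default strict `"ATGA"`, relax to
#'   `"RTGA"` if desired).
#' @param core_3p 3' core motif (the invariant `"GA"`).
#' @param helix1_len length (bp) of the stem closing the core from below.
#' @param helix1_max_mismatch non-canonical pairs allowed in helix 1.
#' @param helix2_len_range allowed helix 2 lengths (bp).
#' @param helix2_max_mismatch non-canonical pairs allowed in helix 2.
#' @param apical_loop_range allowed apical loop lengths (nt).
#' @param apical_offset 0-based offset of the unpaired dinucleotide from the
#'   loop 5' end.
#' @return a list of class `secis_params`.
#' @export
secis_params <- function(core_5p = "ATGA", core_3p = "GA",
                         helix1_len = 6L, helix1_max_mismatch = 0L,
                         helix2_len_range = c(9L, 15L),
                         helix2_max_mismatch = 2L,
                         apical_loop_range = c(7L, 16L),
                         apical_offset = 2L) {
  stopifnot(helix2_len_range[1] <= helix2_len_range[2],
            apical_loop_range[1] <= apical_loop_range[2],
            helix2_max_mismatch < helix2_len_range[1],
            apical_offset + 2 <= apical_loop_range[1],
            helix1_len >= 0)
  structure(list(core_5p = toupper(core_5p), core_3p = toupper(core_3p),
                 helix1_len = as.integer(helix1_len),
                 helix1_max_mismatch = as.integer(helix1_max_mismatch),
                 helix2_len_range = as.integer(helix2_len_range),
                 helix2_max_mismatch = as.integer(helix2_max_mismatch),
                 apical_loop_range = as.integer(apical_loop_range),
                 apical_offset = as.integer(apical_offset)),
            class = "secis_params")
}

# Canonical pairing (Watson-Crick + G.U wobble); N pairs with nothing.
.pairs_with <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# 1-based start positions of all (overlapping) IUPAC pattern matches.
iupac_positions <- function(pattern, text) {
  look <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
            W = "[AT]", S = "[CG]", K = "[GT]", M = "[AC]", N = "[ACGT]")
  rx <- paste0("(?=", paste(look[strsplit(pattern, "")[[1]]], collapse = ""), ")")
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

.iupac_match <- function(pattern, text) {
  look <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
            W = "AT", S = "CG", K = "GT", M = "AC", N = "ACGT")
  p <- strsplit(pattern, "")[[1]]
  t <- strsplit(text, "")[[1]]
  length(p) == length(t) &&
    all(mapply(function(pp, tt) grepl(tt, look[[pp]], fixed = TRUE), p, t))
}

count_mismatches <- function(chars, from5, from3, len) {
  # arms run inward: position i of the 5' arm pairs position len-1-i of the 3' arm
  a <- chars[from5 + seq_len(len)]
  b <- chars[from3 + len + 1 - seq_len(len)]
  sum(!.pairs_with(a, b))
}

#' Scan a nucleotide sequence for SECIS-element candidates
#'
#' Enumerates all placements of the grammar (see [secis_params()]) anchored
#' at 5'-core motif matches; overlapping candidates are resolved to the
#' best-scoring one.  The score is the number of matched helix-2 pairs minus
#' twice the mismatches, plus a bonus of 2 for an AA/CC apical dinucleotide;
#' it is used only for overlap resolution, never as a threshold.
#'
#' @param sequence a character string over A/C/G/T/N (case-insensitive).
#' @param params a [secis_params()] object.
#' @param seqid sequence name recorded in the output.
#' @param both_strands also scan the reverse complement, reporting minus-
#'   strand hits in forward coordinates.
#' @return a data.frame of class `secis_hits` with columns `seqid`, `start`,
#'   `end` (0-based half-open), `strand`, `score`, `core5_start`,
#'   `core3_start`, `apical_start`, `apical_class`, sorted by position.
#'   Anchor coordinates of minus-strand hits refer to the reverse-complement
#'   reading of the forward sequence.
#' @export
scan_secis <- function(sequence, params = secis_params(), seqid = "seq",
                       both_strands = TRUE) {
  plus <- scan_secis_strand(sequence, params, seqid)
  out <- plus
  if (both_strands) {
    n <- nchar(sequence)
    minus <- scan_secis_strand(revcomp(sequence), params, seqid)
    if (nrow(minus)) {
      L5 <- nchar(params$core_5p); L3 <- nchar(params$core_3p)
      minus <- transform(minus,
        strand = "-",
        start = n - minus$end, end = n - minus$start,
        core5_start = n - minus$core5_start - L5,
        core3_start = n - minus$core3_start - L3,
        apical_start = n - minus$apical_start - 2L)
      out <- rbind(plus, minus)
    }
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("secis_hits", "data.frame"), params = params)
}

scan_secis_strand <- function(sequence, params, seqid) {
  seq <- toupper(sequence)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  p <- params
  L5 <- nchar(p$core_5p); L3 <- nchar(p$core_3p); h1 <- p$helix1_len
  hits <- list()
  min_len <- 2 * h1 + L5 + 2 * p$helix2_len_range[1] +
    p$apical_loop_range[1] + L3
  if (n >= min_len) {
    core5_cand <- iupac_positions(p$core_5p, seq)
    for (c5 in core5_cand) {
      s0 <- c5 - 1L - h1             # 0-based element start
      if (s0 < 0) next
      for (h2 in p$helix2_len_range[1]:p$helix2_len_range[2]) {
        for (l in p$apical_loop_range[1]:p$apical_loop_range[2]) {
          arm5 <- c5 - 1L + L5       # 0-based start of helix2 5' arm
          loop <- arm5 + h2
          arm3 <- loop + l
          c3 <- arm3 + h2            # 0-based start of 3' core
          e0 <- c3 + L3 + h1         # 0-based element end (exclusive)
          if (e0 > n) next
          if (substr(seq, c3 + 1, c3 + L3) != p$core_3p) next
          if (grepl("N", substr(seq, s0 + 1, e0), fixed = TRUE)) next
          mm2 <- count_mismatches(chars, arm5, arm3, h2)
          if (mm2 > p$helix2_max_mismatch) next
          if (h1 > 0) {
            mm1 <- count_mismatches(chars, s0, c3 + L3, h1)
            if (mm1 > p$helix1_max_mismatch) next
          }
          ap <- loop + p$apical_offset
          apical <- substr(seq, ap + 1, ap + 2)
          apc <- if (apical %in% c("AA", "CC")) apical else "other"
          score <- (h2 - mm2) - 2 * mm2 + 2 * (apc != "other")
          hits[[length(hits) + 1L]] <- data.frame(
            seqid = seqid, start = s0, end = e0, strand = "+",
            score = score, core5_start = c5 - 1L, core3_start = c3,
            apical_start = ap, apical_class = apc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seqid = character(), start = integer(), end = integer(),
               strand = character(), score = numeric(),
               core5_start = integer(), core3_start = integer(),
               apical_start = integer(), apical_class = character(),
               stringsAsFactors = FALSE)
  if (nrow(out) > 1) {               # greedy best-score overlap resolution
    out <- out[order(-out$score, out$start), , drop = FALSE]
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      ov <- keep & out$start < out$end[i] & out$end > out$start[i]
      keep[i] <- !any(ov)
    }
    out <- out[keep, , drop = FALSE]
  }
  out[order(out$start), , drop = FALSE]
}

as_one_hit <- function(hit) {
  if (is.data.frame(hit)) {
    if (nrow(hit) != 1) stop("expected a single hit row")
    as.list(hit)
  } else as.list(hit)
}

# Re-express a minus-strand hit on the reverse complement so downstream
# checks always work in the reading orientation of the element.
hit_plus_frame <- function(h, sequence, params) {
  if (is.null(h$strand) || h$strand != "-")
    return(list(hit = h, seq = toupper(sequence)))
  n <- nchar(sequence)
  L5 <- nchar(params$core_5p); L3 <- nchar(params$core_3p)
  h2 <- h
  h2$strand <- "+"
  h2$start <- n - h$end; h2$end <- n - h$start
  h2$core5_start <- n - h$core5_start - L5
  h2$core3_start <- n - h$core3_start - L3
  h2$apical_start <- n - h$apical_start - 2L
  list(hit = h2, seq = revcomp(sequence))
}

#' Apical dinucleotide class of a SECIS hit
#'
#' @param hit one row of a [scan_secis()] result.
#' @param sequence the sequence the hit was found on.
#' @return `"AA"`, `"CC"` or `"other"`.
#' @export
apical_class <- function(hit, sequence, params = attr(hit, "params")) {
  h <- as_one_hit(hit)
  if (is.null(params)) params <- secis_params()
  pf <- hit_plus_frame(h, sequence, params)
  h <- pf$hit; seq <- pf$seq
  if (h$end > nchar(seq)) stop("hit does not fit the supplied sequence")
  dinuc <- substr(seq, h$apical_start + 1, h$apical_start + 2)
  if (dinuc %in% c("AA", "CC")) dinuc else "other"
}

#' Validate the core quartet and helix geometry of a SECIS hit
#'
#' Re-checks the 5' and 3' core motifs and the helix-2 pairing of a
#' previously located element (e.g. after mutating the sequence); failures
#' are named in the diagnostics.
#'
#' @param hit one row of a [scan_secis()] result.
#' @param sequence the (possibly mutated) sequence.
#' @param params the grammar parameters the hit was produced with.
#' @return list with `valid` (logical) and `diagnostics` (character vector
#'   among `"5p_core_motif"`, `"3p_core_motif"`, `"helix2_mismatch"`,
#'   `"helix1_pairing"`).
#' @export
validate_core <- function(hit, sequence, params = attr(hit, "params")) {
  h <- as_one_hit(hit)
  if (is.null(params)) params <- secis_params()
  p <- params
  pf <- hit_plus_frame(h, sequence, p)
  h <- pf$hit; seq <- pf$seq
  if (h$end > nchar(seq)) stop("hit does not fit the supplied sequence")
  chars <- strsplit(seq, "")[[1]]
  L5 <- nchar(p$core_5p); L3 <- nchar(p$core_3p)
  diag <- character()
  if (!.iupac_match(p$core_5p, substr(seq, h$core5_start + 1, h$core5_start + L5)))
    diag <- c(diag, "5p_core_motif")
  if (substr(seq, h$core3_start + 1, h$core3_start + L3) != p$core_3p)
    diag <- c(diag, "3p_core_motif")
  # Recover helix2/loop geometry from the stored coordinates.
  arm5 <- h$core5_start + L5
  span_inner <- h$core3_start - arm5
  loop_start <- h$apical_start - p$apical_offset
  h2 <- loop_start - arm5
  loop_len <- span_inner - 2 * h2
  arm3 <- loop_start + loop_len
  if (h2 >= 1 && loop_len >= 1 && arm3 + h2 == h$core3_start) {
    if (count_mismatches(chars, arm5, arm3, h2) > p$helix2_max_mismatch)
      diag <- c(diag, "helix2_mismatch")
  } else diag <- c(diag, "helix2_mismatch")
  if (p$helix1_len > 0) {
    if (count_mismatches(chars, h$start, h$core3_start + L3, p$helix1_len) >
        p$helix1_max_mismatch)
      diag <- c(diag, "helix1_pairing")
  }
  list(valid = length(diag) == 0L, diagnostics = diag)
}

#' Generate a random grammar-conformant SECIS element
#'
#' Draws helix and loop lengths uniformly from the grammar ranges, fills the
#' helices with complementary random base pairs (introducing at most
#' `mismatches` non-canonical pairs in helix 2), and writes the requested
#' apical dinucleotide.  Uses the current RNG state.
#'
#' @param params a [secis_params()] object.
#' @param apical apical dinucleotide to plant (`"AA"`, `"CC"`, or any
#'   2-mer).
#' @param mismatches number of non-canonical helix-2 pairs to introduce.
#' @return list with `seq` and the 0-based relative coordinates
#'   `core5_start`, `core3_start`, `apical_start`, `length`.
#' @export
generate_secis <- function(params = secis_params(), apical = "AA",
                           mismatches = 0L) {
  p <- params
  rb <- function(k) sample(c("A", "C", "G", "T"), k, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  h2 <- sample(p$helix2_len_range[1]:p$helix2_len_range[2], 1)
  l  <- sample(p$apical_loop_range[1]:p$apical_loop_range[2], 1)
  core5 <- chartr("R", sample(c("A", "G"), 1), p$core_5p)
  arm5_2 <- rb(h2)
  arm3_2 <- rev(unname(comp[arm5_2]))
  if (mismatches > 0) {              # corrupt interior pairs only
    stopifnot(mismatches <= p$helix2_max_mismatch, h2 > 2)
    at <- sample(2:(h2 - 1), mismatches)
    for (i in at) {
      j <- h2 + 1 - i               # 3' arm index pairing 5' position i
      arm3_2[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                  c(comp[arm5_2[i]],
                                    if (arm5_2[i] %in% c("G", "T"))
                                      chartr("GT", "TG", arm5_2[i]))), 1)
    }
  }
  loop <- rb(l)
  loop[p$apical_offset + 1:2] <- strsplit(apical, "")[[1]]
  # keep the loop edges unpaired so the helix cannot be parsed one bp longer
  while (.pairs_with(loop[1], loop[l]))
    loop[l] <- sample(c("A", "C", "G", "T"), 1)
  arm5_1 <- rb(p$helix1_len)
  arm3_1 <- rev(unname(comp[arm5_1]))
  seq <- paste(c(arm5_1, strsplit(core5, "")[[1]], arm5_2, loop, arm3_2,
                 strsplit(p$core_3p, "")[[1]], arm3_1), collapse = "")
  core5_start <- p$helix1_len
  arm5 <- core5_start + nchar(p$core_5p)
  list(seq = seq, core5_start = core5_start,
       core3_start = arm5 + 2 * h2 + l,
       apical_start = arm5 + h2 + p$apical_offset,
       length = nchar(seq))
}
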