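# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.  Synonymous site
# fractions count only single-base changes to sense codons; multi-position
# codon differences are averaged over all minimal mutational pathways that
# avoid stop codons, re-weighted equally.

.codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

codon_aa <- function(codon) {
  gc <- genetic_code()
  unname(gc[codon])
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position, the synonymous fraction is the share of
#' single-base changes leading to sense codons that preserve the amino acid;
#' changes to stop codons are excluded from the denominator.  The two counts
#' always sum to 3.
#'
#' @param codon a 3-base codon string over ACGT (vectorized).
#' @return a matrix with columns `syn` and `nonsyn`, one row per codon.
#' @export
count_sites <- function(codon) {
  tab <- site_table()
  codon <- toupper(codon)
  bad <- !codon %in% rownames(tab)
  if (any(bad)) {
    gc <- genetic_code()
    if (any(gc[codon[bad]] == "*", na.rm = TRUE))
      stop("stop codon has no site counts (excluded codon)")
    stop("not a codon over ACGT: ", paste(codon[bad], collapse = ", "))
  }
  tab[codon, , drop = FALSE]
}

site_table <- function() {
  if (!is.null(.codon_env$sites)) return(.codon_env$sites)
  gc <- genetic_code()
  sense <- sense_codons()
  bases <- c("A", "C", "G", "T")
  tab <- t(vapply(sense, function(cod) {
    s <- 0
    for (p in 1:3) {
      nts <- strsplit(cod, "")[[1]]
      alt <- vapply(setdiff(bases, nts[p]), function(b) {
        x <- nts; x[p] <- b; paste(x, collapse = "")
      }, character(1))
      alt <- alt[gc[alt] != "*"]
      if (length(alt))
        s <- s + sum(gc[alt] == gc[cod]) / length(alt)
    }
    c(syn = s, nonsyn = 3 - s)
  }, numeric(2)))
  .codon_env$sites <- tab
  tab
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Differences are partitioned by enumerating all orderings of the differing
#' positions, discarding pathways that pass through a stop codon, and
#' averaging the per-step synonymous/nonsynonymous counts over the remaining
#' pathways (all pathways are used if every one passes through a stop).
#'
#' @param codon_a,codon_b sense codons over ACGT.
#' @return named numeric vector `c(Sd, Nd)`; `Sd + Nd` equals the number of
#'   differing positions.
#' @export
count_differences <- function(codon_a, codon_b) {
  gc <- genetic_code()
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cod in c(codon_a, codon_b))
    if (is.na(gc[cod]) || gc[cod] == "*")
      stop("count_differences needs sense codons, got ", cod)
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diffpos <- which(a != b)
  if (!length(diffpos)) return(c(Sd = 0, Nd = 0))
  paths <- perms(diffpos)
  step_counts <- function(ord) {
    cur <- a; s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      cod1 <- paste(cur, collapse = ""); cod2 <- paste(nxt, collapse = "")
      if (gc[cod2] == "*") return(NULL)      # pathway through a stop codon
      if (gc[cod1] == gc[cod2]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- lapply(paths, step_counts)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {                  # all pathways blocked; fall back to all
    res <- lapply(paths, function(ord) {
      cur <- a; s <- 0; n <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        if (gc[paste(cur, collapse = "")] == gc[paste(nxt, collapse = "")] &&
            gc[paste(nxt, collapse = "")] != "*") s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    })
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(perms(x[-i]), function(p) c(x[i], p)))
  out
}

# 61 x 61 memoized pairwise difference table (Sd then Nd), for speed.
diff_tables <- function() {
  if (!is.null(.codon_env$diffs)) return(.codon_env$diffs)
  sense <- sense_codons()
  n <- length(sense)
  Sd <- Nd <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      d <- count_differences(sense[i], sense[j])
      Sd[i, j] <- Sd[j, i] <- d[["Sd"]]
      Nd[i, j] <- Nd[j, i] <- d[["Nd"]]
    }
  }
  .codon_env$diffs <- list(Sd = Sd, Nd = Nd)
  .codon_env$diffs
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori Ka/Ks for an aligned codon pair
#'
#' Computes fractional synonymous/nonsynonymous site and difference counts
#' (sites averaged between the two sequences), the proportions `pS`/`pN`,
#' their Jukes-Cantor corrections `Ks`/`Ka`, and the `Ka/Ks` ratio.  Codons
#' containing gaps or ambiguous bases, and codon pairs where either codon is
#' a stop, are excluded (with a count).
#'
#' @param seq_a,seq_b aligned coding sequences of equal length divisible
#'   by 3 (characters outside ACGT are treated as gaps).
#' @return an object of class `kaks_result`: list with `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio`, `n_codons` (compared),
#'   `n_excluded`, and logical flags `saturated` and `ratio_undefined`.
#' @export
nei_gojobori <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned sequences differ in length")
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  sense <- sense_codons()
  keep <- ca %in% sense & cb %in% sense
  n_excluded <- sum(!keep)
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) stop("no comparable codons")
  st <- site_table()
  S <- (sum(st[ca, "syn"]) + sum(st[cb, "syn"])) / 2
  N <- 3 * length(ca) - S
  dt <- diff_tables()
  Sd <- sum(dt$Sd[cbind(ca, cb)])
  Nd <- sum(dt$Nd[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) if (is.na(p) || p >= 3 / 4) NA_real_ else
    -3 / 4 * log(1 - 4 / 3 * p)
  Ks <- jc(pS); Ka <- jc(pN)
  saturated <- (!is.na(pS) && pS >= 3 / 4) || (!is.na(pN) && pN >= 3 / 4)
  ratio_undefined <- is.na(Ks) || is.na(Ka) || Ks == 0
  structure(list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS,
                 pN = pN, Ks = Ks, Ka = Ka,
                 ratio = if (ratio_undefined) NA_real_ else Ka / Ks,
                 n_codons = length(ca), n_excluded = n_excluded,
                 saturated = saturated, ratio_undefined = ratio_undefined),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Nei-Gojobori: %d codons (%d excluded)\n", x$n_codons, x$n_excluded))
  cat(sprintf("  S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n", x$S_sites, x$N_sites, x$Sd, x$Nd))
  cat(sprintf("  Ks=%.4f Ka=%.4f Ka/Ks=%s\n", x$Ks, x$Ka,
              if (x$ratio_undefined) "undefined" else sprintf("%.4f", x$ratio)))
  invisible(x)
}
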