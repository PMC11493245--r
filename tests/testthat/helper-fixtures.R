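# shared fixtures and independent oracles

# tiny deterministic assembly from explicit sequences
tiny_ref <- function(seqs, circular = TRUE) {
  ref_assembly(Biostrings::DNAStringSet(seqs),
               rep_len(circular, length(seqs)))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# score one explicit gapped alignment under affine costs
# (gap run of length L costs gap_open + gap_extend * L)
score_alignment <- function(ca, cb, submat, gap_open, gap_extend) {
  stopifnot(length(ca) == length(cb))
  s <- 0
  gap_runs <- function(ch) {
    r <- rle(ch == "-")
    sum(r$lengths[r$values])        # total gap bases
  }
  n_runs <- function(ch) {
    r <- rle(ch == "-")
    sum(r$values)                   # number of gap runs
  }
  for (i in seq_along(ca)) {
    if (ca[i] != "-" && cb[i] != "-") s <- s + submat[ca[i], cb[i]]
  }
  s - gap_open * (n_runs(ca) + n_runs(cb)) -
    gap_extend * (gap_runs(ca) + gap_runs(cb))
}

# exhaustive enumeration of every global alignment of a and b (no both-gap
# columns), returning the maximum score; independent of the DP implementation
enumerate_best_score <- function(a, b, submat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ga, gb) {
    if (i > length(ca) && j > length(cb)) {
      sc <- score_alignment(ga, gb, submat, gap_open, gap_extend)
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, c(ga, ca[i]), c(gb, cb[j]))
    if (i <= length(ca)) rec(i + 1, j, c(ga, ca[i]), c(gb, "-"))
    if (j <= length(cb)) rec(i, j + 1, c(ga, "-"), c(gb, cb[j]))
    invisible()
  }
  rec(1, 1, character(0), character(0))
  best
}

# textbook Bartlett statistic, written from the formula rather than
# stats::bartlett.test
bartlett_textbook <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  s2 <- vapply(groups, stats::var, numeric(1))
  sp2 <- sum((n - 1) * s2) / (N - k)
  num <- (N - k) * log(sp2) - sum((n - 1) * log(s2))
  den <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  num / den
}

# random protein-ish sequences and mutated copies for clustering fixtures
random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, n_subs) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), n_subs)
  for (p in pos) ch[p] <- sample(setdiff(aa, ch[p]), 1)
  paste(ch, collapse = "")
}

# planted exclusion-index pattern mirroring a two-group surface-exclusion
# experiment: cognate-group cells ~100, others ~1
two_group_pattern <- function() {
  sfx <- c("sfx_94", "sfx_Asa4c", "sfx_AhD4-1", "sfx_Aut1", "sfx_AQU1")
  tra <- c("traN_94", "traN_Asa4c", "traN_AhD4-1", "traN_AQU1")
  ei <- matrix(1, length(sfx), length(tra), dimnames = list(sfx, tra))
  for (s in c("sfx_94", "sfx_Asa4c", "sfx_AhD4-1", "sfx_Aut1"))
    ei[s, c("traN_94", "traN_Asa4c", "traN_AhD4-1")] <- 100
  ei["sfx_AQU1", "traN_AQU1"] <- 100
  ei
}
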