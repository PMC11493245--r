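#' Filter homolog search hits by identity and coverage
#'
#' Retains hits with percent identity at or above `min_identity` and query
#' coverage at or above `min_coverage` (boundary values retained). The
#' defaults reproduce the conventional screen for trustworthy homologs of a
#' query protein: at least 45% identity over at least 85% of the query.
#' Idempotent.
#'
#' @param hits data.frame with columns `query`, `subject`, `pident`
#'   (0-100) and `qcov` (proportion, 0-1).
#' @param min_identity minimum percent identity (default 45).
#' @param min_coverage minimum query coverage proportion (default 0.85).
#' @return the filtered data.frame.
#' @export
filter_hits <- function(hits, min_identity = 45, min_coverage = 0.85) {
  stopifnot(all(c("query", "subject", "pident", "qcov") %in% names(hits)))
  if (any(hits$pident < 0 | hits$pident > 100)) stop("pident must be in [0, 100]")
  if (any(hits$qcov < 0 | hits$qcov > 1)) stop("qcov must be in [0, 1]")
  out <- hits[hits$pident >= min_identity & hits$qcov >= min_coverage, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BLAST-style tabular hit file
#'
#' Expects tab-separated columns `query`, `subject`, `pident`, `qcovs`
#' (coverage as a 0-100 percentage, as emitted by `blastp -outfmt
#' "6 qseqid sseqid pident qcovs"`); coverage is converted to a proportion.
#'
#' @param path TSV path (with header).
#' @return data.frame with columns `query`, `subject`, `pident`, `qcov`.
#' @export
read_blast_tab <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("query", "subject", "pident", "qcovs") %in% names(df)))
  data.frame(query = df$query, subject = df$subject, pident = df$pident,
             qcov = df$qcovs / 100, stringsAsFactors = FALSE)
}

aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Default protein scoring matrix
#'
#' BLOSUM62 restricted to the 20 standard residues plus X, with X scoring 0
#' against every residue (unknowns neither rewarded nor penalized).
#'
#' @return a 21 x 21 numeric matrix.
#' @export
default_protein_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[aa_alphabet[aa_alphabet != "X"],
                  aa_alphabet[aa_alphabet != "X"]]
  m <- cbind(rbind(m, X = 0), X = 0)
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

validate_protein <- function(seq, id) {
  if (is.na(seq) || nchar(seq) == 0)
    stop("empty protein sequence: ", id)
  bad <- setdiff(strsplit(seq, "", fixed = TRUE)[[1]], aa_alphabet)
  if (length(bad))
    stop(sprintf("illegal residue(s) %s in record '%s'",
                 paste(unique(bad), collapse = ","), id))
  invisible(seq)
}

#' Optimal global protein alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment maximizing the substitution-matrix score
#' minus affine gap costs; a gap of length L costs
#' `gap_open + gap_extend * L`. Percent identity is computed over aligned
#' columns, excluding terminal-gap columns (the leading and trailing runs
#' where one sequence has not started or has already ended), so identity
#' reflects the mutually covered region.
#'
#' @param a,b named character scalars (names are record ids) or unnamed
#'   protein sequences; alphabet is the 20 standard residues plus X.
#' @param submat substitution matrix with residue dimnames
#'   (default [default_protein_matrix()]).
#' @param gap_open,gap_extend affine gap parameters (defaults 10 and 0.5).
#' @return an object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b`, `score`, `matches`, `aligned_columns`, `percent_identity`.
#' @export
global_align <- function(a, b, submat = default_protein_matrix(),
                         gap_open = 10, gap_extend = 0.5) {
  ida <- if (!is.null(names(a))) names(a)[1] else "a"
  idb <- if (!is.null(names(b))) names(b)[1] else "b"
  a <- toupper(as.character(a)[1]); b <- toupper(as.character(b)[1])
  validate_protein(a, ida)
  validate_protein(b, idb)
  alpha <- rownames(submat)
  res <- .gotoh_align(a, b, submat, alpha, gap_open, gap_extend)
  ca <- strsplit(res$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(res$aligned_b, "", fixed = TRUE)[[1]]
  inner <- which(ca != "-" & cb != "-")
  if (length(inner)) {
    cols <- seq(min(inner), max(inner))
  } else {
    cols <- integer(0)
  }
  matches <- sum(ca[cols] == cb[cols] & ca[cols] != "-")
  aligned_columns <- length(cols)
  structure(list(id_a = ida, id_b = idb,
                 aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, matches = matches,
                 aligned_columns = aligned_columns,
                 percent_identity = if (aligned_columns > 0)
                   100 * matches / aligned_columns else 0),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s vs %s: score %.1f, %.1f%% identity over %d columns\n",
              x$id_a, x$id_b, x$score, x$percent_identity, x$aligned_columns))
  invisible(x)
}

as_protein_set <- function(records) {
  nm <- names(records)
  seqs <- setNames(toupper(as.character(records)), nm)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("protein records need unique names")
  for (i in seq_along(seqs)) validate_protein(seqs[i], names(seqs)[i])
  seqs
}

#' All-vs-all percent-identity matrix
#'
#' @param records an [Biostrings::AAStringSet] or named character vector of
#'   protein sequences (>= 2 records).
#' @param ... passed to [global_align()].
#' @return symmetric numeric matrix of percent identities, diagonal 100.
#' @export
identity_matrix <- function(records, ...) {
  seqs <- as_protein_set(records)
  n <- length(seqs)
  if (n < 2) stop("need >= 2 records")
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid <- global_align(seqs[i], seqs[j], ...)$percent_identity
      m[i, j] <- m[j, i] <- pid
    }
  }
  m
}

#' Greedy identity clustering of proteins
#'
#' CD-HIT-style greedy incremental clustering: records are sorted by
#' decreasing length (ties broken by id), and each record joins the first
#' existing cluster whose representative it matches at or above the identity
#' cutoff; otherwise it founds a new cluster and becomes its representative.
#'
#' @param records an [Biostrings::AAStringSet] or named character vector.
#' @param cutoff identity cutoff as a proportion (default 0.90).
#' @param ... passed to [global_align()].
#' @return an object of class `cluster_set`: list with `clusters` (named list
#'   of member id vectors, representative first) and `representative`
#'   (named character vector cluster -> id).
#' @export
greedy_cluster <- function(records, cutoff = 0.90, ...) {
  seqs <- as_protein_set(records)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      pid <- global_align(seqs[i], seqs[reps[ci]], ...)$percent_identity
      if (pid / 100 >= cutoff) {
        members[[ci]] <- c(members[[ci]], names(seqs)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, names(seqs)[i])
      members[[length(reps)]] <- names(seqs)[i]
    }
  }
  names(members) <- paste0("cluster", seq_along(members))
  structure(list(clusters = members,
                 representative = setNames(reps, names(members))),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("%d cluster(s):\n", length(x$clusters)))
  for (g in names(x$clusters))
    cat(sprintf("  %s [rep %s]: %s\n", g, x$representative[[g]],
                paste(x$clusters[[g]], collapse = ", ")))
  invisible(x)
}

#' Read a protein FASTA file
#' @param path FASTA path.
#' @return an [Biostrings::AAStringSet].
#' @export
read_protein_fasta <- function(path) Biostrings::readAAStringSet(path)

#' Write an identity matrix as TSV
#' @param m identity matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_identity_tsv <- function(m, path) {
  write.table(as.data.frame(m), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Heatmap of pairwise percent identities
#' @param m identity matrix.
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
plot_identity_heatmap <- function(m, path) {
  pdf(path, width = 6, height = 5)
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     display_numbers = nrow(m) <= 20,
                     main = "pairwise percent identity")
  dev.off()
  invisible(path)
}
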