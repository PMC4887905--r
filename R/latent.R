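#' Fit the truncated-SVD latent space of the combined matrix
#'
#' Decomposes `X = U S V'` and retains the leading `r` factors.  The
#' default rank follows the published choice of 400 latent dimensions
#' and is capped automatically at `min(m, n) - 1` for small datasets
#' (with a message); an explicitly requested rank above the cap is an
#' error.  Singular vectors are sign-canonicalized (the
#' largest-magnitude component of each left singular vector is made
#' positive) so the fit is fully deterministic.  Factors whose singular
#' value is numerically zero are dropped with a warning.
#'
#' @param cm a `combined_matrix` (see [concatenate_blocks()]).
#' @param r retained rank; `NULL` (default) means `min(400, min(m, n) - 1)`.
#' @return an object of class `latent_space` with orthonormal `U`
#'   (m x r), singular values `S` (non-increasing, positive), `V`
#'   (n x r), the retained rank `r`, and the labels/block map carried
#'   over from `cm`.
#' @export
ls_fit <- function(cm, r = NULL) {
  X <- as.matrix(cm$X)
  m <- nrow(X); n <- ncol(X)
  rmax <- min(m, n) - 1L
  if (rmax < 1) stop("matrix too small for a truncated SVD", call. = FALSE)
  if (max(abs(X)) == 0) stop("X has no nonzero entry", call. = FALSE)
  if (is.null(r)) {
    r <- min(400L, rmax)
    if (r < 400L)
      message("rank capped at ", r, " (= min(m, n) - 1) for this dataset")
  } else {
    r <- as.integer(r)
    if (r < 1 || r > rmax)
      stop("r must be between 1 and ", rmax, " for a ", m, " x ", n,
           " matrix", call. = FALSE)
  }
  sv <- svd(X, nu = r, nv = r)
  S <- sv$d[seq_len(r)]
  keep <- S > max(sv$d[1], .Machine$double.eps) * 1e-12
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " numerically zero singular value(s); ",
            "effective rank ", sum(keep), call. = FALSE)
    S <- S[keep]
    sv$u <- sv$u[, keep, drop = FALSE]
    sv$v <- sv$v[, keep, drop = FALSE]
    r <- sum(keep)
  }
  U <- sv$u; V <- sv$v
  for (k in seq_len(r)) {
    i0 <- which.max(abs(U[, k]))
    if (U[i0, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  structure(list(U = U, S = S, V = V, r = r,
                 row_labels = cm$row_labels,
                 col_labels = cm$col_labels,
                 col_blocks = cm$col_blocks),
            class = "latent_space")
}

#' @export
print.latent_space <- function(x, ...) {
  cat(sprintf("<latent_space> rank %d over %d miRNAs x %d features; sigma1 = %.4g\n",
              x$r, nrow(x$U), nrow(x$V), x$S[1]))
  invisible(x)
}

disease_col_index <- function(ls, disease) {
  disease <- norm_label(disease)
  idx <- which(ls$col_blocks == "disease" & ls$col_labels == disease)
  if (!length(idx)) {
    labels <- ls$col_labels[ls$col_blocks == "disease"]
    near <- labels[utils::adist(disease, labels) <= 3]
    if (!length(near)) near <- utils::head(sort(labels), 5)
    stop(structure(class = c("mirlsa_unknown_disease", "error", "condition"),
                   list(message = paste0(
                     "unknown disease '", disease, "'; closest labels: ",
                     paste(utils::head(near, 5), collapse = ", ")),
                     call = NULL)))
  }
  idx[1]
}

#' Latent vector of a disease
#'
#' The disease's row of `V`, scaled componentwise by the singular
#' values (the same symmetric scaling is applied to miRNA vectors, so
#' cosine comparisons are consistent).
#'
#' @param ls a [ls_fit()] result.
#' @param disease disease id (a column label of the disease block).
#' @return numeric vector of length `r`.
#' @export
disease_vector <- function(ls, disease) {
  idx <- disease_col_index(ls, disease)
  ls$V[idx, ] * ls$S
}

## miRNA embedding: rows of U scaled by the singular values
mirna_vectors <- function(ls) {
  sweep(ls$U, 2, ls$S, `*`)
}

#' Query the latent space for a disease
#'
#' Ranks every miRNA by the cosine similarity between its latent vector
#' (row of `U` scaled by the singular values) and the disease vector.
#' Zero-norm vectors score 0.  Ordering is by descending score with
#' ties broken by miRNA id.
#'
#' @param ls a [ls_fit()] result.
#' @param disease disease id.
#' @return an object of class `ranked_list`: a data.frame with columns
#'   `rank`, `mirna`, `score`, with the disease id as attribute
#'   `disease`.
#' @export
ls_query <- function(ls, disease) {
  dv <- disease_vector(ls, disease)
  Mv <- mirna_vectors(ls)
  scores <- cosine_scores(Mv, dv)
  ranked_list(ls$row_labels, scores, norm_label(disease))
}

cosine_scores <- function(Mv, dv) {
  dn <- sqrt(sum(dv^2))
  rn <- sqrt(rowSums(Mv^2))
  s <- as.numeric(Mv %*% dv)
  ok <- rn > 0 & dn > 0
  out <- numeric(length(s))
  out[ok] <- s[ok] / (rn[ok] * dn)
  out
}

ranked_list <- function(mirnas, scores, disease) {
  o <- order(-scores, mirnas)
  df <- data.frame(rank = seq_along(mirnas),
                   mirna = mirnas[o],
                   score = scores[o],
                   stringsAsFactors = FALSE)
  attr(df, "disease") <- disease
  class(df) <- c("ranked_list", class(df))
  df
}

#' @export
print.ranked_list <- function(x, n = 10, ...) {
  cat(sprintf("<ranked_list> disease '%s', %d miRNAs; top %d:\n",
              attr(x, "disease"), nrow(x), min(n, nrow(x))))
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}

#' Fold a new feature vector into an existing latent space
#'
#' Standard latent-semantic fold-in: `x' V diag(1/S)` gives the
#' left-factor coordinates, which are then rescaled by `S` for scoring
#' consistency with [ls_query()] (net effect: `x' V`).  Folding in an
#' existing row of `X` reproduces that row's scaled embedding when `r`
#' equals the full rank; the operation is linear in `x`.
#'
#' @param ls a [ls_fit()] result.
#' @param x_new numeric vector indexed by the latent space's column
#'   labels (length n).
#' @return numeric vector of length `r`.
#' @export
fold_in <- function(ls, x_new) {
  x_new <- as.numeric(x_new)
  if (length(x_new) != nrow(ls$V))
    stop("x_new has length ", length(x_new), ", expected ", nrow(ls$V),
         call. = FALSE)
  (as.numeric(x_new %*% ls$V) / ls$S) * ls$S
}

#' Persist a latent space as plain-text sidecar files
#'
#' @param ls a [ls_fit()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_latent <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(ls$U, file.path(dir, "U.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  writeLines(format(ls$S, digits = 17), file.path(dir, "S.txt"))
  write.table(ls$V, file.path(dir, "V.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  writeLines(ls$row_labels, file.path(dir, "rows.txt"))
  writeLines(paste(ls$col_labels, ls$col_blocks, sep = "\t"),
             file.path(dir, "cols.tsv"))
  invisible(dir)
}

#' Load a latent space saved by [save_latent()]
#'
#' @param dir directory written by [save_latent()].
#' @return a `latent_space`.
#' @export
load_latent <- function(dir) {
  U <- as.matrix(utils::read.table(file.path(dir, "U.tsv"), sep = "\t"))
  V <- as.matrix(utils::read.table(file.path(dir, "V.tsv"), sep = "\t"))
  S <- as.numeric(readLines(file.path(dir, "S.txt")))
  cols <- strsplit(readLines(file.path(dir, "cols.tsv")), "\t", fixed = TRUE)
  dimnames(U) <- NULL; dimnames(V) <- NULL
  structure(list(U = U, S = S, V = V, r = length(S),
                 row_labels = readLines(file.path(dir, "rows.txt")),
                 col_labels = vapply(cols, `[[`, character(1), 1),
                 col_blocks = vapply(cols, `[[`, character(1), 2)),
            class = "latent_space")
}
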