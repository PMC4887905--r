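#' Construct a feature matrix block
#'
#' A sparse nonnegative miRNA-by-feature block with row/column labels
#' and a block tag.  All blocks share the miRNA row ordering of the
#' dataset; values lie in `[0, 1]`.
#'
#' @param values matrix coercible to `dgCMatrix`.
#' @param rows ordered miRNA ids.
#' @param cols ordered feature ids.
#' @param block one of `"disease"`, `"neighbor"`, `"target"`, `"word"`,
#'   `"family"`.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, rows, cols, block) {
  block <- match.arg(block,
                     c("disease", "neighbor", "target", "word", "family"))
  if (!methods::is(values, "Matrix"))
    values <- Matrix::Matrix(values, sparse = TRUE)
  values <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(values) != length(rows) || ncol(values) != length(cols))
    stop("dimensions do not match label lengths", call. = FALSE)
  if (length(values@x) && (min(values@x) < 0 || max(values@x) > 1 + 1e-12))
    stop("feature values must lie in [0, 1]", call. = FALSE)
  dimnames(values) <- list(rows, cols)
  structure(list(values = Matrix::drop0(values),
                 rows = as.character(rows),
                 cols = as.character(cols),
                 block = block),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix:%s> %d x %d, %d nonzeros\n",
              x$block, length(x$rows), length(x$cols),
              length(x$values@x)))
  invisible(x)
}

#' Disease block MD: known associations propagated by Lin similarity
#'
#' `x[i, j]` is 1 when the association (i, j) is in the dataset;
#' otherwise it is the aggregate (default: maximum) Lin similarity
#' between disease j and the diseases known to be associated with miRNA
#' i.  Propagated entries below `floor` are dropped to keep the block
#' sparse.  A miRNA with no known association gets an all-zero row.
#'
#' @param dataset a [mirna_dataset()].
#' @param ontology a [build_ontology()] result.
#' @param floor sparsity floor for propagated entries (default 0.05).
#' @param aggregate `"max"` (best-match propagation, default) or
#'   `"mean"`.
#' @param sim_matrix optional precomputed [lin_matrix()] over
#'   `dataset$diseases` (a cache for cross-validation refits).
#' @return a `feature_matrix` with block `"disease"`.
#' @export
build_disease_matrix <- function(dataset, ontology, floor = 0.05,
                                 aggregate = c("max", "mean"),
                                 sim_matrix = NULL) {
  aggregate <- match.arg(aggregate)
  d <- dataset$diseases
  if (is.null(sim_matrix)) sim_matrix <- lin_matrix(ontology, d)
  M <- matrix(0, length(dataset$mirnas), length(d))
  sets <- association_sets(dataset)
  for (i in seq_along(sets)) {
    M[i, ] <- md_row(match(sets[[i]], d), sim_matrix, floor, aggregate)
  }
  feature_matrix(M, mirna_ids(dataset), d, "disease")
}

## one MD row from the indices of the miRNA's known diseases
md_row <- function(K, sim_matrix, floor, aggregate) {
  row <- numeric(ncol(sim_matrix))
  if (!length(K)) return(row)
  sub <- sim_matrix[K, , drop = FALSE]
  row <- if (aggregate == "max") apply(sub, 2, max) else colMeans(sub)
  row[row < floor] <- 0
  row[K] <- 1
  row
}

#' Parameters of the genomic-distance sigmoid
#'
#' The neighbor weight is `1 / (1 + exp(k * (dist - dist0)))`: 1 for
#' overlapping loci, 0.5 exactly at `dist = dist0`, and decaying beyond.
#' The default midpoint is 60 kb (`6e4` bp), matching the reported drop
#' of miRNA co-expression beyond ~50 kb; `k` defaults to `2e-4` per bp.
#'
#' @param dist0 sigmoid midpoint in bp (> 0).
#' @param k steepness in 1/bp (> 0).
#' @return an object of class `neighbor_params`.
#' @export
neighbor_params <- function(dist0 = 6e4, k = 2e-4) {
  stopifnot(is.numeric(dist0), dist0 > 0, is.numeric(k), k > 0)
  structure(list(dist0 = dist0, k = k), class = "neighbor_params")
}

#' Sigmoid weight of a genomic distance
#'
#' @param dist genomic distance in bp (number of bases strictly between
#'   the two loci; 0 when they overlap or are adjacent).
#' @param params a [neighbor_params()] object.
#' @return weight in `(0, 1)`; exactly 0.5 at `dist == params$dist0`.
#' @export
neighbor_weight <- function(dist, params = neighbor_params()) {
  1 / (1 + exp(params$k * (dist - params$dist0)))
}

#' Neighbor block MN: genomic proximity between miRNAs
#'
#' For every pair of miRNAs with loci on the same chromosome the
#' genomic distance is the minimum over location pairs of the gap
#' between closest ends (0 if the loci overlap); strand is ignored.
#' The distance is turned into a weight with the sigmoid of
#' [neighbor_weight()]; weights below `floor` are dropped, the diagonal
#' of located miRNAs is set to 1, and the matrix is symmetric.  miRNAs
#' without any location get a zero row/column (a warning reports how
#' many).
#'
#' @param dataset a [mirna_dataset()].
#' @param params a [neighbor_params()] object.
#' @param floor sparsity floor (default `1e-3`).
#' @return a `feature_matrix` with block `"neighbor"`.
#' @export
build_neighbor_matrix <- function(dataset, params = neighbor_params(),
                                  floor = 1e-3) {
  ids <- mirna_ids(dataset)
  m <- length(ids)
  locs <- lapply(dataset$mirnas, `[[`, "locations")
  located <- which(vapply(locs, nrow, integer(1)) > 0)
  if (length(located) < m)
    warning(m - length(located), " miRNA(s) without genomic location: ",
            "zero neighbor row/column", call. = FALSE)
  D <- matrix(Inf, m, m)
  chroms <- unique(unlist(lapply(locs[located], `[[`, "chrom")))
  for (ch in chroms) {
    on_ch <- located[vapply(locs[located],
                            function(l) any(l$chrom == ch), logical(1))]
    if (length(on_ch) < 2) next
    for (a in seq_along(on_ch)[-1]) {
      i <- on_ch[a]
      li <- locs[[i]][locs[[i]]$chrom == ch, , drop = FALSE]
      for (b in seq_len(a - 1)) {
        j <- on_ch[b]
        lj <- locs[[j]][locs[[j]]$chrom == ch, , drop = FALSE]
        gap <- min(outer(seq_len(nrow(li)), seq_len(nrow(lj)),
                         function(p, q)
                           pmax(0, pmax(li$start[p], lj$start[q]) -
                                  pmin(li$end[p], lj$end[q]) - 1)))
        D[i, j] <- min(D[i, j], gap)
        D[j, i] <- D[i, j]
      }
    }
  }
  W <- matrix(0, m, m)
  finite <- is.finite(D)
  W[finite] <- neighbor_weight(D[finite], params)
  W[W < floor] <- 0
  diag(W)[located] <- 1
  feature_matrix(W, ids, ids, "neighbor")
}

#' Two-step resource-allocation projection of a bipartite network
#'
#' Implements the weighted one-mode target projection: resources on each
#' target flow to its miRNAs (each miRNA receives `1/k(target)` of the
#' target's resource), then flow back (each target receives
#' `1/k(miRNA)` of the miRNA's resource).  The resulting `t x t` matrix
#' `W` holds, in column `l`, the composition of target `l`'s new weight
#' in terms of the original target resources:
#' `W[j, l] = (1 / k(t_j)) * sum_i M[i, j] * M[i, l] / k(m_i)`.
#' `W` is not symmetric; each row of `W` sums to 1 for targets with at
#' least one miRNA (resource conservation).  The weighted
#' miRNA-target matrix is `MT = M %*% W`, clamped at 1 (existing edges
#' keep positive weight; new implied associations may appear).
#'
#' @param M binary miRNA-by-target matrix (rows miRNAs, columns
#'   targets); zero-degree rows/columns are allowed and contribute and
#'   receive nothing.
#' @return list with `W` (t x t), `MT` (m x t, entries in `[0, 1]`) and
#'   `step1` (m x t; `step1[i, j] = M[i, j] / k(t_j)` is the fraction of
#'   target j's resource reaching miRNA i in the first step).
#' @export
project_targets <- function(M) {
  M <- as.matrix(M)
  if (length(M) && any(!(M %in% c(0, 1))))
    stop("M must be binary", call. = FALSE)
  km <- rowSums(M)
  kt <- colSums(M)
  Mi <- M / ifelse(km > 0, km, Inf)          # step-2 flow shares
  step1 <- sweep(M, 2, ifelse(kt > 0, kt, Inf), "/")
  S <- crossprod(Mi, M)                      # S[j, l] = sum_i M_ij M_il / k(m_i)
  W <- sweep(S, 1, ifelse(kt > 0, kt, Inf), "/")
  MT <- M %*% W
  MT[MT > 1] <- 1                            # block-scale clamp, see vignette
  dimnames(W) <- list(colnames(M), colnames(M))
  dimnames(MT) <- dimnames(M)
  dimnames(step1) <- dimnames(M)
  list(W = W, MT = MT, step1 = step1)
}

#' Target block MT from the dataset's validated miRNA-target edges
#'
#' @param dataset a [mirna_dataset()].
#' @return a `feature_matrix` with block `"target"`.
#' @export
build_target_matrix <- function(dataset) {
  genes <- dataset$genes
  m <- length(dataset$mirnas)
  M <- matrix(0, m, length(genes))
  for (i in seq_along(dataset$mirnas)) {
    K <- match(dataset$mirnas[[i]]$targets, genes)
    M[i, K] <- 1
  }
  MT <- if (length(genes)) project_targets(M)$MT else M
  feature_matrix(MT, mirna_ids(dataset), genes, "target")
}

#' Word block MW: TF-IDF weights of abstract tokens
#'
#' Abstracts are tokenized with [tokenize()]; term frequency is the raw
#' count in the miRNA's concatenated abstracts; the smoothed inverse
#' document frequency is `idf = ln((1 + m) / (1 + df)) + 1`; rows are
#' L2-normalized so all entries lie in `[0, 1]`.  Empty documents give
#' zero rows.
#'
#' @param dataset a [mirna_dataset()].
#' @return a `feature_matrix` with block `"word"`.
#' @export
build_word_matrix <- function(dataset) {
  vocab <- dataset$vocabulary
  m <- length(dataset$mirnas)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (i in seq_along(dataset$mirnas)) {
    toks <- tokenize(dataset$mirnas[[i]]$abstract_text)
    if (!length(toks)) next
    tab <- table(toks)
    j <- match(names(tab), vocab)
    keep <- !is.na(j)
    ii <- c(ii, rep.int(i, sum(keep)))
    jj <- c(jj, j[keep])
    xx <- c(xx, as.numeric(tab)[keep])
  }
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(m, length(vocab)))
  df <- Matrix::colSums(C > 0)
  idf <- log((1 + m) / (1 + df)) + 1
  Tf <- C %*% Matrix::Diagonal(length(vocab), idf)
  norms <- sqrt(Matrix::rowSums(Tf^2))
  norms[norms == 0] <- 1
  Tf <- Matrix::Diagonal(m, 1 / norms) %*% Tf
  feature_matrix(Tf, mirna_ids(dataset), vocab, "word")
}

#' Family block MF: binary family membership
#'
#' Exactly one 1 per row for miRNAs with a family, zero rows otherwise.
#' Raw values are retained (no weighting).
#'
#' @param dataset a [mirna_dataset()].
#' @return a `feature_matrix` with block `"family"`.
#' @export
build_family_matrix <- function(dataset) {
  fams <- dataset$families
  m <- length(dataset$mirnas)
  M <- matrix(0, m, length(fams))
  for (i in seq_along(dataset$mirnas)) {
    f <- dataset$mirnas[[i]]$family
    if (!is.na(f)) M[i, match(f, fams)] <- 1
  }
  feature_matrix(M, mirna_ids(dataset), fams, "family")
}

#' Concatenate feature blocks into the combined matrix X
#'
#' Horizontal concatenation in the fixed order disease, neighbor,
#' target, word, family (blocks are reordered if given otherwise; the
#' fixed order makes column indices reproducible).  All blocks must
#' share an identical miRNA row ordering.
#'
#' @param blocks list of `feature_matrix` objects (one per block tag at
#'   most).
#' @return an object of class `combined_matrix` with elements `X`
#'   (sparse m x n), `row_labels`, `col_labels` and `col_blocks` (block
#'   tag per column).
#' @export
concatenate_blocks <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  tags <- vapply(blocks, `[[`, character(1), "block")
  if (anyDuplicated(tags)) stop("duplicate block tags", call. = FALSE)
  order_tags <- c("disease", "neighbor", "target", "word", "family")
  blocks <- blocks[order(match(tags, order_tags))]
  tags <- tags[order(match(tags, order_tags))]
  rows <- blocks[[1]]$rows
  for (b in blocks[-1]) {
    if (!identical(b$rows, rows)) {
      bad <- which(b$rows != rows)[1]
      stop(sprintf("row ordering mismatch in block '%s' at row %d: '%s' vs '%s'",
                   b$block, bad, b$rows[bad], rows[bad]), call. = FALSE)
    }
  }
  X <- do.call(cbind, lapply(blocks, `[[`, "values"))
  col_blocks <- rep(tags, vapply(blocks, function(b) length(b$cols),
                                 integer(1)))
  structure(list(X = X,
                 row_labels = rows,
                 col_labels = unlist(lapply(blocks, `[[`, "cols"),
                                     use.names = FALSE),
                 col_blocks = col_blocks),
            class = "combined_matrix")
}

#' @export
print.combined_matrix <- function(x, ...) {
  widths <- table(factor(x$col_blocks,
                         levels = c("disease", "neighbor", "target",
                                    "word", "family")))
  cat(sprintf("<combined_matrix> %d x %d (%s), %d nonzeros\n",
              nrow(x$X), ncol(x$X),
              paste(names(widths), widths, sep = "=", collapse = ", "),
              length(x$X@x)))
  invisible(x)
}

#' Build all five blocks and concatenate them
#'
#' @param dataset a [mirna_dataset()].
#' @param ontology a [build_ontology()] result.
#' @param md_floor,mn_floor sparsity floors of the disease and neighbor
#'   blocks.
#' @param neighbor a [neighbor_params()] object.
#' @param md_aggregate propagation rule for the disease block.
#' @return a `combined_matrix`.
#' @export
build_combined <- function(dataset, ontology,
                           md_floor = 0.05, mn_floor = 1e-3,
                           neighbor = neighbor_params(),
                           md_aggregate = "max") {
  concatenate_blocks(list(
    build_disease_matrix(dataset, ontology, floor = md_floor,
                         aggregate = md_aggregate),
    build_neighbor_matrix(dataset, params = neighbor, floor = mn_floor),
    build_target_matrix(dataset),
    build_word_matrix(dataset),
    build_family_matrix(dataset)))
}

#' Export the combined matrix as MatrixMarket plus label sidecars
#'
#' Writes `combined.mtx`, `rows.txt` (one miRNA id per line) and
#' `cols.tsv` (`label<TAB>block`), in deterministic column order.
#'
#' @param cm a `combined_matrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_combined <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$X, file.path(dir, "combined.mtx"))
  writeLines(cm$row_labels, file.path(dir, "rows.txt"))
  writeLines(paste(cm$col_labels, cm$col_blocks, sep = "\t"),
             file.path(dir, "cols.tsv"))
  invisible(dir)
}
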