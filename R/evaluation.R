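#' Stratified fold assignment for one disease
#'
#' Positives (miRNAs associated with the disease) and negatives are
#' each split as evenly as possible across `n_folds` folds; total fold
#' sizes differ by at most 1.  Deterministic for a fixed seed.
#'
#' @param mirnas character vector of all miRNA ids.
#' @param positives subset of `mirnas` associated with the disease.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return named integer vector (fold index in `1..n_folds` per miRNA,
#'   in the order of `mirnas`).
#' @export
make_folds <- function(mirnas, positives, n_folds = 5, seed = 1) {
  positives <- intersect(mirnas, positives)
  if (length(positives) < n_folds)
    stop("only ", length(positives), " positive miRNA(s): need at least ",
         n_folds, "; the evaluation protocol keeps diseases associated ",
         "with at least 20 miRNAs", call. = FALSE)
  negatives <- setdiff(mirnas, positives)
  folds <- with_seed(seed, {
    pos <- sample(positives)
    neg <- sample(negatives)
    c(structure(rep_len(seq_len(n_folds), length(pos)), names = pos),
      structure(rep_len(rev(seq_len(n_folds)), length(neg)), names = neg))
  })
  folds[mirnas]
}

#' ROC curve and AUC of a score/label set
#'
#' Threshold sweep over distinct scores; tied scores are treated as one
#' step and the area is the trapezoidal rule, so the AUC equals the
#' Mann-Whitney concordance probability (ties counted 1/2).
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels logical (or 0/1) vector; `TRUE` marks a known positive.
#' @return list with `points` (data.frame threshold, tp, fp, tn, fn,
#'   tpr, fpr, starting at (0, 0)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0)
    stop("ROC needs at least one positive and one negative", call. = FALSE)
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)    # last index of each tie group
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, s[last]),
                           tp = c(0L, tp), fp = c(0L, fp),
                           tn = N - c(0L, fp), fn = P - c(0L, tp),
                           tpr = tpr, fpr = fpr),
       auc = auc)
}

#' Precompute everything shared across cross-validation refits
#'
#' Caches the pairwise Lin similarity of the dataset's diseases, the
#' five full-data feature blocks, the full-data latent fit, and the
#' full-data ranked query of every disease on demand.
#'
#' @param dataset a [mirna_dataset()].
#' @param ontology a [build_ontology()] result.
#' @param r retained rank passed to [ls_fit()] (`NULL` = capped 400).
#' @param md_floor,mn_floor,neighbor,md_aggregate feature-block
#'   parameters (see [build_combined()]).
#' @return an object of class `cv_context`.
#' @export
cv_context <- function(dataset, ontology, r = NULL,
                       md_floor = 0.05, mn_floor = 1e-3,
                       neighbor = neighbor_params(),
                       md_aggregate = "max") {
  sim <- lin_matrix(ontology, dataset$diseases)
  md <- build_disease_matrix(dataset, ontology, floor = md_floor,
                             aggregate = md_aggregate, sim_matrix = sim)
  blocks <- list(md,
                 build_neighbor_matrix(dataset, params = neighbor,
                                       floor = mn_floor),
                 build_target_matrix(dataset),
                 build_word_matrix(dataset),
                 build_family_matrix(dataset))
  cm <- concatenate_blocks(blocks)
  full_fit <- suppressMessages(ls_fit(cm, r = r))
  structure(list(dataset = dataset, ontology = ontology,
                 sim_matrix = sim, blocks = blocks, combined = cm,
                 full_fit = full_fit, r = r,
                 md_floor = md_floor, md_aggregate = md_aggregate),
            class = "cv_context")
}

#' @export
print.cv_context <- function(x, ...) {
  cat("<cv_context>\n"); print(x$combined); invisible(x)
}

#' Score the held-out miRNAs of one cross-validation fold
#'
#' The combined matrix is rebuilt with the fold's removals applied: for
#' every test-fold miRNA, (a) its disease-block entry for the queried
#' disease and every value propagated from that association are removed
#' (the Lin propagation of its remaining diseases is recomputed, so no
#' leakage survives), and (b) its entire word-block row is zeroed (all
#' study-derived text removed).  The latent space is refit and queried.
#'
#' @param ctx a [cv_context()].
#' @param disease disease id.
#' @param folds fold map from [make_folds()].
#' @param fold_index which fold is held out.
#' @return named numeric vector of scores for the held-out miRNAs.
#' @export
run_fold <- function(ctx, disease, folds, fold_index) {
  disease <- norm_label(disease)
  ids <- mirna_ids(ctx$dataset)
  test_ids <- names(folds)[folds == fold_index]
  d_all <- ctx$dataset$diseases
  d_idx <- match(disease, d_all)
  if (is.na(d_idx)) stop("unknown disease: ", disease, call. = FALSE)

  md <- ctx$blocks[[1]]$values
  sets <- association_sets(ctx$dataset)
  touch <- intersect(test_ids, ids[vapply(sets, function(s) disease %in% s,
                                          logical(1))])
  if (length(touch)) {
    md <- as(md, "CsparseMatrix")
    for (id in touch) {
      i <- match(id, ids)
      K <- match(setdiff(sets[[i]], disease), d_all)
      md[i, ] <- md_row(K, ctx$sim_matrix, ctx$md_floor, ctx$md_aggregate)
    }
  }
  mw <- ctx$blocks[[4]]$values
  mw[match(test_ids, ids), ] <- 0
  blocks <- ctx$blocks
  blocks[[1]] <- feature_matrix(md, ctx$blocks[[1]]$rows,
                                ctx$blocks[[1]]$cols, "disease")
  blocks[[4]] <- feature_matrix(mw, ctx$blocks[[4]]$rows,
                                ctx$blocks[[4]]$cols, "word")
  fit <- suppressMessages(ls_fit(concatenate_blocks(blocks), r = ctx$r))
  ranked <- ls_query(fit, disease)
  structure(ranked$score[match(test_ids, ranked$mirna)], names = test_ids)
}

#' Per-disease five-fold cross-validation with ROC/AUC and flagging
#'
#' Runs the masked-refit protocol of [run_fold()] for every fold,
#' computes a ROC curve and AUC on each fold's held-out miRNAs, and
#' reports the mean of the fold AUCs as the disease's AUC.  Flag lists
#' are then computed from a single ranking in which every known
#' positive carries the score from the fold where it was held out
#' (its association and study text removed), while non-associated
#' candidates carry their full-data score (set
#' `use_full_for_negatives = FALSE` for a pure held-out pooled ranking).
#'
#' @param ctx a [cv_context()].
#' @param disease disease id.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param threshold rank-fraction flag threshold (default 0.85, strict).
#' @param use_full_for_negatives score candidates from the full model
#'   (default `TRUE`).
#' @return an object of class `cv_result`: disease, seed, folds,
#'   per-fold `roc` and `auc`, pooled `auc` (mean of folds),
#'   `held_scores`, the flag `ranking`, `flagged_false`, `flagged_novel`.
#' @export
run_cv <- function(ctx, disease, n_folds = 5, seed = 1, threshold = 0.85,
                   use_full_for_negatives = TRUE) {
  disease <- norm_label(disease)
  ids <- mirna_ids(ctx$dataset)
  sets <- association_sets(ctx$dataset)
  positives <- ids[vapply(sets, function(s) disease %in% s, logical(1))]
  folds <- make_folds(ids, positives, n_folds = n_folds, seed = seed)
  held <- structure(numeric(length(ids)), names = ids)
  fold_roc <- vector("list", n_folds)
  fold_auc <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    sc <- run_fold(ctx, disease, folds, k)
    held[names(sc)] <- sc
    lab <- names(sc) %in% positives
    if (!any(lab) || all(lab))
      stop("fold ", k, " has a single class; stratification failed",
           call. = FALSE)
    rr <- roc_curve(sc, lab)
    fold_roc[[k]] <- rr$points
    fold_auc[k] <- rr$auc
  }
  full_scores <- {
    rk <- ls_query(ctx$full_fit, disease)
    structure(rk$score[match(ids, rk$mirna)], names = ids)
  }
  flag_scores <- if (use_full_for_negatives) {
    ifelse(ids %in% positives, held[ids], full_scores[ids])
  } else held[ids]
  ranking <- ranked_list(ids, unname(flag_scores), disease)
  structure(list(disease = disease, seed = seed, folds = folds,
                 positives = positives,
                 fold_roc = fold_roc, fold_auc = fold_auc,
                 auc = mean(fold_auc),
                 held_scores = held,
                 ranking = ranking,
                 flagged_false = flag_putative_false(ranking, positives,
                                                     threshold),
                 flagged_novel = flag_novel(ranking, positives, threshold)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> disease '%s': AUC %.3f (folds: %s); %d flagged false, %d flagged novel\n",
              x$disease, x$auc,
              paste(sprintf("%.3f", x$fold_auc), collapse = " "),
              nrow(x$flagged_false), nrow(x$flagged_novel)))
  invisible(x)
}

#' Flag putatively false known associations
#'
#' A KNOWN positive is flagged when the fraction of negatives ranked
#' strictly above it exceeds `threshold` (strict inequality at the
#' boundary), i.e. when it is reported with a false positive rate above
#' the threshold and sits at the very end of the ranked list.
#'
#' @param ranked a `ranked_list` (full ranking of all miRNAs).
#' @param positives character vector of known-positive miRNA ids.
#' @param threshold rank-fraction threshold (default 0.85).
#' @return data.frame (`mirna`, `fraction`) of flagged positives,
#'   sorted by decreasing fraction.
#' @export
flag_putative_false <- function(ranked, positives, threshold = 0.85) {
  is_pos <- ranked$mirna %in% positives
  N <- sum(!is_pos)
  negs_above <- c(0, cumsum(!is_pos))[seq_len(nrow(ranked))]
  frac <- if (N > 0) negs_above / N else rep(0, nrow(ranked))
  sel <- is_pos & frac > threshold
  out <- data.frame(mirna = ranked$mirna[sel], fraction = frac[sel],
                    stringsAsFactors = FALSE)
  out[order(-out$fraction, out$mirna), , drop = FALSE]
}

#' Flag novel candidate associations
#'
#' A NON-associated miRNA is flagged when the fraction of known
#' positives ranked strictly below it exceeds `threshold` (strict), i.e.
#' when it is reported with a true positive rate above the threshold
#' and sits close to the beginning of the list.
#'
#' @inheritParams flag_putative_false
#' @return data.frame (`mirna`, `fraction`) of flagged candidates,
#'   sorted by decreasing fraction.
#' @export
flag_novel <- function(ranked, positives, threshold = 0.85) {
  is_pos <- ranked$mirna %in% positives
  P <- sum(is_pos)
  pos_below <- P - cumsum(is_pos)
  frac <- if (P > 0) pos_below / P else rep(0, nrow(ranked))
  sel <- !is_pos & frac > threshold
  out <- data.frame(mirna = ranked$mirna[sel], fraction = frac[sel],
                    stringsAsFactors = FALSE)
  out[order(-out$fraction, out$mirna), , drop = FALSE]
}

#' Cross-validate every disease that passes the association filter
#'
#' @param ctx a [cv_context()].
#' @param min_positives keep diseases with at least this many associated
#'   miRNAs (default 20, the published filter).
#' @param n_folds,seed,threshold passed to [run_cv()]; the per-disease
#'   fold seed is derived deterministically from `seed`.
#' @return named list of `cv_result`s.
#' @export
run_cv_all <- function(ctx, min_positives = 20, n_folds = 5, seed = 1,
                       threshold = 0.85) {
  sets <- association_sets(ctx$dataset)
  counts <- table(unlist(sets, use.names = FALSE))
  keep <- names(counts)[counts >= min_positives]
  keep <- intersect(ctx$dataset$diseases, keep)
  res <- lapply(seq_along(keep), function(k)
    run_cv(ctx, keep[k], n_folds = n_folds,
           seed = (seed * 1000L + k) %% .Machine$integer.max,
           threshold = threshold))
  names(res) <- keep
  res
}
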