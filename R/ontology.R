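ROOT_TERM <- "(root)"

#' Build a disease ontology from a MeSH-style tree-number file
#'
#' The tree file is a TSV `term<TAB>tree_number` with dot-separated
#' MeSH-style codes (e.g. `C04.588.180`); a term may own several tree
#' numbers, which makes the structure a DAG (multiple parents).  A
#' virtual root is placed above all top-level numbers; terms with no
#' tree number would be attached directly to the root.
#'
#' Information content is annotation-derived: each (miRNA, disease)
#' association contributes one annotation to the disease term, counts
#' are propagated bottom-up (once per annotation, even along multiple
#' paths), and `P(term) = propagated_count / total` where `total` is the
#' root's propagated count.  Unannotated terms receive add-one smoothing
#' (the smallest positive probability, `1 / total`), which keeps every
#' log defined while preserving `P(child) <= P(parent)`.
#'
#' @param tree_file path to the TSV tree file.
#' @param associations a named list miRNA id -> disease ids (as returned
#'   by [load_associations()]), the frequency corpus; `NULL` gives a
#'   uniform (all-smoothed) ontology.
#' @return an object of class `disease_ontology` with elements `terms`,
#'   `parents`, `ancestors` (each including the virtual root),
#'   `annotation`, `propagated`, `total` and `probability`.
#' @export
build_ontology <- function(tree_file, associations = NULL) {
  tf <- read_tab_file(tree_file)
  nf <- lengths(tf$fields)
  if (length(nf) && any(nf < 2))
    stop(sprintf("tree file %s, line %d: expected 2 tab-separated fields",
                 tree_file, tf$lineno[which(nf < 2)[1]]), call. = FALSE)
  term <- norm_label(vapply(tf$fields, `[[`, character(1), 1))
  code <- trimws(vapply(tf$fields, `[[`, character(1), 2))
  code_owner <- structure(term, names = code)
  if (anyDuplicated(code)) {
    dup <- unique(code[duplicated(code)])
    bad <- vapply(dup, function(cc)
      length(unique(term[code == cc])) > 1, logical(1))
    if (any(bad))
      stop("tree number owned by several terms: ",
           paste(dup[bad], collapse = ", "), call. = FALSE)
  }
  terms <- sort(unique(term))
  ## parent of a code: longest proper dot-prefix owned by a term, else root
  parent_of_code <- function(cc) {
    parts <- strsplit(cc, ".", fixed = TRUE)[[1]]
    while (length(parts) > 1) {
      parts <- parts[-length(parts)]
      pc <- paste(parts, collapse = ".")
      if (pc %in% names(code_owner)) return(unname(code_owner[pc]))
    }
    ROOT_TERM
  }
  parents <- lapply(terms, function(t) {
    codes <- code[term == t]
    sort(unique(vapply(codes, parent_of_code, character(1))))
  })
  names(parents) <- terms
  parents[[ROOT_TERM]] <- character()
  all_terms <- c(terms, ROOT_TERM)

  ## ancestors (including self and root), memoized; a term owning a tree
  ## number inside its own subtree would create a cycle, which MeSH
  ## forbids -- detect and reject instead of recursing forever
  anc_env <- new.env(parent = emptyenv())
  ancestors_of <- function(t, path = character()) {
    if (t %in% path)
      stop("cyclic tree numbers around term '", t, "'", call. = FALSE)
    if (!is.null(anc_env[[t]])) return(anc_env[[t]])
    res <- t
    for (p in parents[[t]]) res <- c(res, ancestors_of(p, c(path, t)))
    res <- sort(unique(res))
    anc_env[[t]] <- res
    res
  }
  ancestors <- lapply(all_terms, ancestors_of)
  names(ancestors) <- all_terms

  annotation <- structure(numeric(length(all_terms)), names = all_terms)
  if (!is.null(associations)) {
    tab <- table(unlist(associations, use.names = FALSE))
    hit <- intersect(names(tab), terms)
    annotation[hit] <- as.numeric(tab[hit])
  }
  propagated <- structure(numeric(length(all_terms)), names = all_terms)
  for (t in all_terms) {
    if (annotation[[t]] > 0)
      propagated[ancestors[[t]]] <- propagated[ancestors[[t]]] + annotation[[t]]
  }
  total <- max(propagated[[ROOT_TERM]], 1)
  probability <- pmin(pmax(propagated, 1) / total, 1)
  probability[[ROOT_TERM]] <- 1

  structure(list(terms = all_terms, parents = parents,
                 ancestors = ancestors, annotation = annotation,
                 propagated = propagated, total = total,
                 probability = probability, root = ROOT_TERM),
            class = "disease_ontology")
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat(sprintf("<disease_ontology> %d terms (+virtual root), %g annotations\n",
              length(x$terms) - 1, sum(x$annotation)))
  invisible(x)
}

check_term <- function(ontology, x) {
  if (!x %in% ontology$terms)
    stop("term not in ontology: '", x, "'", call. = FALSE)
}

#' Most informative common ancestor of two terms
#'
#' Returns the common ancestor with minimal annotation probability
#' (maximal information content); the virtual root is always a valid
#' fallback.  Ties are broken by term id for determinism.
#'
#' @param ontology a [build_ontology()] result.
#' @param x,y term ids.
#' @return a term id.
#' @export
mica <- function(ontology, x, y) {
  check_term(ontology, x); check_term(ontology, y)
  common <- intersect(ontology$ancestors[[x]], ontology$ancestors[[y]])
  p <- ontology$probability[common]
  common[order(p, common)][1]
}

#' Lin semantic similarity between two disease terms
#'
#' `sim(x, y) = 2 log P(D0) / (log P(x) + log P(y))` where `D0` is the
#' most informative common ancestor ([mica()]).  The value lies in
#' `[0, 1]`, is symmetric, and equals 1 for `x == y`.  Degenerate
#' denominators (both terms with probability 1) give 0 unless `x == y`.
#' The logarithm base cancels; natural log is used.
#'
#' @param ontology a [build_ontology()] result.
#' @param x,y term ids.
#' @return similarity in `[0, 1]`.
#' @export
lin_similarity <- function(ontology, x, y) {
  check_term(ontology, x); check_term(ontology, y)
  if (x == y) return(1)
  px <- ontology$probability[[x]]
  py <- ontology$probability[[y]]
  den <- log(px) + log(py)
  if (den == 0) return(0)
  pm <- ontology$probability[[mica(ontology, x, y)]]
  min(max(2 * log(pm) / den, 0), 1)
}

#' Pairwise Lin similarity over a set of disease labels
#'
#' Labels absent from the ontology (ontology orphans, e.g. disease names
#' that could not be mapped to a tree term) get similarity 0 to every
#' other label and 1 to themselves.
#'
#' @param ontology a [build_ontology()] result.
#' @param labels character vector of disease ids.
#' @return symmetric `length(labels)` square matrix with unit diagonal.
#' @export
lin_matrix <- function(ontology, labels) {
  n <- length(labels)
  S <- diag(1, n)
  dimnames(S) <- list(labels, labels)
  known <- which(labels %in% ontology$terms)
  if (length(known) > 1) {
    for (a in seq_along(known)[-1]) {
      i <- known[a]
      for (b in seq_len(a - 1)) {
        j <- known[b]
        s <- lin_similarity(ontology, labels[i], labels[j])
        S[i, j] <- s
        S[j, i] <- s
      }
    }
  }
  S
}
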