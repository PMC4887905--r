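# Fixtures are built in code at test time; oracles here are independent
# re-derivations (enumeration / simulation) of the quantities they check.

tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# ontology whose annotated probabilities are P(A)=1/2, P(B)=P(C)=1/4,
# with mica(B, C) = A, so lin(B, C) = 2 log(1/2) / (2 log(1/4)) = 0.5
chain_ontology <- function() {
  tree <- tmp_tsv(c("A\tC01", "B\tC01.010", "C\tC01.020", "D\tC02"))
  build_ontology(tree, list(m1 = "b", m2 = "c", m3 = "d", m4 = "d"))
}

# random MeSH-style DAG: terms may own two tree numbers (two parents)
random_dag_tree <- function(n_terms, seed) {
  with_seed_test(seed, {
    codes <- c("A", "B")
    owner <- c("t1", "t2")
    for (i in 3:n_terms) {
      parent <- sample(codes, 1)
      code <- paste0(parent, ".", sprintf("%03d", i))
      codes <- c(codes, code)
      owner <- c(owner, paste0("t", i))
    }
    lines <- paste(owner, codes, sep = "\t")
    # extra tree numbers (second parents) only point from later terms to
    # earlier subtrees, so the code hierarchy stays acyclic (MeSH-like)
    half <- n_terms %/% 2
    extra <- sample((half + 1):n_terms, max(1, n_terms %/% 4))
    for (i in extra) {
      own <- codes[i]
      ok <- which(seq_along(codes) <= half & !startsWith(codes, own) &
                    !startsWith(own, codes))
      if (!length(ok)) next
      donor <- sample(ok, 1)
      lines <- c(lines, paste0("t", i, "\t", codes[donor], ".",
                               sprintf("%03d", 900 + i)))
    }
    lines
  })
}

random_dag_ontology <- function(n_terms = 12, seed = 1) {
  tree <- tmp_tsv(random_dag_tree(n_terms, seed))
  ann <- with_seed_test(seed + 1, {
    k <- sample(n_terms, max(2, n_terms %/% 2))
    stats::setNames(as.list(paste0("t", k)), paste0("m", seq_along(k)))
  })
  build_ontology(tree, ann)
}

# seed scoping for helpers (tests must not disturb the session RNG)
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# ancestor sets recomputed from the parents map only (independent of the
# memoized sets inside the ontology object)
oracle_ancestors <- function(ont, t) {
  seen <- character()
  stack <- t
  while (length(stack)) {
    cur <- stack[1]
    stack <- stack[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    stack <- c(stack, ont$parents[[cur]])
  }
  sort(seen)
}

oracle_mica <- function(ont, x, y) {
  common <- intersect(oracle_ancestors(ont, x), oracle_ancestors(ont, y))
  p <- ont$probability[common]
  common[order(p, common)][1]
}

# explicit two-step resource diffusion: W[j, l] = share of target j's
# initial unit resource that ends on target l
oracle_diffusion <- function(M) {
  m <- nrow(M); t <- ncol(M)
  km <- rowSums(M); kt <- colSums(M)
  W <- matrix(0, t, t)
  for (j in seq_len(t)) {
    res_t <- numeric(t); res_t[j] <- 1
    res_m <- numeric(m)
    for (i in seq_len(m)) for (jj in seq_len(t))
      if (M[i, jj] == 1) res_m[i] <- res_m[i] + res_t[jj] / kt[jj]
    out <- numeric(t)
    for (i in seq_len(m)) for (jj in seq_len(t))
      if (M[i, jj] == 1) out[jj] <- out[jj] + res_m[i] / km[i]
    W[j, ] <- out
  }
  dimnames(W) <- list(colnames(M), colnames(M))
  W
}

# O(n^2) Mann-Whitney concordance with ties counted 1/2
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ps <- scores[labels]; ns <- scores[!labels]
  tot <- 0
  for (p in ps) for (n in ns)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(ps) * length(ns))
}

random_bipartite <- function(m, t, p, seed) {
  with_seed_test(seed, {
    M <- matrix(rbinom(m * t, 1, p), m, t)
    # avoid fully empty rows/columns so conservation applies everywhere
    for (i in which(rowSums(M) == 0)) M[i, sample(t, 1)] <- 1
    for (j in which(colSums(M) == 0)) M[sample(m, 1), j] <- 1
    M
  })
}

# wrap a plain matrix as a combined_matrix (single disease block)
cm_wrap <- function(X, col_block = "disease") {
  X <- Matrix::Matrix(X, sparse = TRUE)
  structure(list(X = X,
                 row_labels = paste0("m", seq_len(nrow(X))),
                 col_labels = paste0("c", seq_len(ncol(X))),
                 col_blocks = rep(col_block, ncol(X))),
            class = "combined_matrix")
}

# tiny in-code dataset: 2 clusters of miRNAs/diseases with locations,
# families, abstracts and targets
toy_dataset <- function() {
  loc <- function(chrom, start, end)
    data.frame(chrom = chrom, strand = "+", start = start, end = end)
  mirna_dataset(list(
    mirna_record("mirA", loc("chr1", 1000, 1100), "famX",
                 "apoptosis pathway tumour growth", c("da", "db"),
                 c("g1", "g2")),
    mirna_record("mirB", loc("chr1", 51000, 51100), "famX",
                 "tumour suppressor apoptosis", "da", "g1"),
    mirna_record("mirC", loc("chr2", 1000, 1100), "famY",
                 "cardiac hypertrophy signalling", "dc", "g3"),
    mirna_record("mirD", loc("chr2", 200000, 200100), "famY",
                 "", character(), "g3")))
}

toy_tree <- function() {
  tmp_tsv(c("da\tC01.100", "db\tC01.200", "dc\tC02.100",
            "group1\tC01", "group2\tC02"))
}

small_bundle <- function(dir = tempfile("bundle"), seed = 7, ...) {
  p <- synth_params(n_mirnas = 60, n_diseases = 12, n_clusters = 3,
                    n_targets = 48, n_families = 6, n_words = 130,
                    seed = seed, ...)
  synth_generate(p, dir)
  dir
}

load_bundle_env <- function(dir) {
  ds <- load_bundle(dir)
  ont <- build_ontology(file.path(dir, "mesh_tree.tsv"),
                        lapply(ds$mirnas, `[[`, "diseases"))
  list(dataset = ds, ontology = ont)
}
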