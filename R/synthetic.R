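#' Parameters of the synthetic bundle generator
#'
#' The generator emulates the statistical structure the method assumes:
#' functionally related miRNAs cluster with phenotypically similar
#' diseases.  miRNAs and diseases are partitioned into `n_clusters`
#' co-clusters; within-cluster associations are drawn with probability
#' `assoc_density` and cross-cluster ones with `cross_cluster_noise`.
#' Families, target signatures, abstract vocabulary and genomic
#' neighborhoods are cluster-coherent, and a MeSH-like tree places
#' same-cluster diseases under a common subtree.  `masking_fraction`
#' of the true within-cluster associations is withheld from the
#' association file and written to `ground_truth.tsv` for recovery
#' tests.
#'
#' @param n_mirnas,n_diseases,n_targets,n_families,n_words,n_clusters
#'   entity counts.
#' @param assoc_density within-cluster association probability.
#' @param cross_cluster_noise cross-cluster association probability.
#' @param masking_fraction fraction of true associations withheld.
#' @param abstract_tokens mean number of tokens per abstract.
#' @param seed integer seed (the bundle is byte-identical given a seed).
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(n_mirnas = 200, n_diseases = 30, n_targets = 120,
                         n_families = 10, n_words = 240, n_clusters = 5,
                         assoc_density = 0.6, cross_cluster_noise = 0.02,
                         masking_fraction = 0.2, abstract_tokens = 120,
                         seed = 42) {
  p <- list(n_mirnas = n_mirnas, n_diseases = n_diseases,
            n_targets = n_targets, n_families = n_families,
            n_words = n_words, n_clusters = n_clusters,
            assoc_density = assoc_density,
            cross_cluster_noise = cross_cluster_noise,
            masking_fraction = masking_fraction,
            abstract_tokens = abstract_tokens, seed = as.integer(seed))
  for (nm in c("n_mirnas", "n_diseases", "n_targets", "n_families",
               "n_words", "n_clusters", "abstract_tokens"))
    if (p[[nm]] < 1) stop(nm, " must be positive", call. = FALSE)
  for (nm in c("assoc_density", "cross_cluster_noise", "masking_fraction"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must be in [0, 1]", call. = FALSE)
  if (p$n_clusters > min(p$n_mirnas, p$n_diseases))
    stop("n_clusters must be <= min(n_mirnas, n_diseases)", call. = FALSE)
  if (p$n_families < p$n_clusters)
    stop("need at least one family per cluster", call. = FALSE)
  if (p$n_words < p$n_diseases + 10)
    stop("n_words too small for per-disease vocabulary slices", call. = FALSE)
  structure(p, class = "synth_params")
}

## letter-only pseudo-word for index i (tokenizer-safe: >= 4 chars)
synth_word <- function(i) {
  a <- (i - 1) %% 26
  b <- ((i - 1) %/% 26) %% 26
  cc <- ((i - 1) %/% 676) %% 26
  paste0("v", letters[cc + 1], letters[b + 1], letters[a + 1])
}

#' Generate a complete synthetic input bundle
#'
#' Writes `associations.tsv`, `locations.gff3`, `families.tsv`,
#' `abstracts.tsv`, `targets.tsv`, `mesh_tree.tsv`, `ground_truth.tsv`
#' (the withheld associations) and `params.json` to `dir`.  Fully
#' deterministic given `params$seed`.
#'
#' Per-disease signal: each disease owns a disjoint slice of the
#' cluster vocabulary and a disjoint target signature; a miRNA's
#' abstract draws 80% of its tokens from the slices of its TRUE
#' diseases (including withheld ones) and 20% from a background pool,
#' and its target set samples the signatures of its true diseases.
#' Withheld associations therefore leave literature and target traces,
#' which is the real-world situation the method exploits.
#'
#' @param params a [synth_params()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the true/observed/masked association
#'   tables and the cluster assignments.
#' @export
synth_generate <- function(params = synth_params(), dir) {
  stopifnot(inherits(params, "synth_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(params$seed, synth_generate_impl(params, dir))
}

synth_generate_impl <- function(p, dir) {
  mirnas <- sprintf("mir-%03d", seq_len(p$n_mirnas))
  diseases <- sprintf("disease-%02d", seq_len(p$n_diseases))
  genes <- sprintf("gene%03d", seq_len(p$n_targets))
  families <- sprintf("fam%02d", seq_len(p$n_families))
  words <- vapply(seq_len(p$n_words), synth_word, character(1))

  mir_cl <- rep_len(seq_len(p$n_clusters), p$n_mirnas)
  dis_cl <- rep_len(seq_len(p$n_clusters), p$n_diseases)

  ## true association matrix
  same <- outer(mir_cl, dis_cl, `==`)
  pr <- ifelse(same, p$assoc_density, p$cross_cluster_noise)
  A <- matrix(rbinom(length(pr), 1, pr), nrow = p$n_mirnas)
  true_pairs <- which(A == 1, arr.ind = TRUE)

  ## withhold a fraction of the within-cluster true associations
  within <- which(A == 1 & same, arr.ind = TRUE)
  n_mask <- floor(nrow(within) * p$masking_fraction)
  masked <- if (n_mask > 0)
    within[sample(nrow(within), n_mask), , drop = FALSE]
  else within[0, , drop = FALSE]
  Obs <- A
  Obs[masked] <- 0

  ## disease tree: one umbrella subtree per cluster
  tree <- c(sprintf("disease-group-%d\tC%02d", seq_len(p$n_clusters),
                    seq_len(p$n_clusters)),
            sprintf("%s\tC%02d.%03d", diseases, dis_cl,
                    100 + seq_len(p$n_diseases)))
  writeLines(c("# term\ttree_number", tree), file.path(dir, "mesh_tree.tsv"))

  ## associations (observed) with fake PMIDs
  obs_pairs <- which(Obs == 1, arr.ind = TRUE)
  obs_pairs <- obs_pairs[order(obs_pairs[, 1], obs_pairs[, 2]), , drop = FALSE]
  pmid <- 10000000 + sample.int(8999999, nrow(obs_pairs), replace = TRUE)
  writeLines(c("# mirna\tdisease\tpmid",
               sprintf("%s\t%s\t%d", mirnas[obs_pairs[, 1]],
                       diseases[obs_pairs[, 2]], pmid)),
             file.path(dir, "associations.tsv"))
  masked <- masked[order(masked[, 1], masked[, 2]), , drop = FALSE]
  writeLines(c("# mirna\tdisease (withheld true associations)",
               sprintf("%s\t%s", mirnas[masked[, 1]],
                       diseases[masked[, 2]])),
             file.path(dir, "ground_truth.tsv"))

  ## genomic layout: each cluster on its own chromosome, gaps U[5kb, 40kb]
  gff <- character(p$n_mirnas)
  for (cl in seq_len(p$n_clusters)) {
    members <- which(mir_cl == cl)
    pos <- 100000L
    for (i in members) {
      width <- sample(80:120, 1)
      gff[i] <- sprintf("chr%d\tmirlsa\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                        cl, pos, pos + width,
                        sample(c("+", "-"), 1), mirnas[i], mirnas[i])
      pos <- pos + width + sample(5000:40000, 1)
    }
  }
  writeLines(c("##gff-version 3", gff), file.path(dir, "locations.gff3"))

  ## families: two per cluster, every miRNA assigned one of its cluster's
  fam_of_cluster <- matrix(rep_len(seq_len(p$n_families), 2 * p$n_clusters),
                           nrow = p$n_clusters)
  fam_idx <- vapply(seq_len(p$n_mirnas), function(i)
    fam_of_cluster[mir_cl[i], sample(ncol(fam_of_cluster), 1)], numeric(1))
  writeLines(c("# mirna\tfamily",
               sprintf("%s\t%s", mirnas, families[fam_idx])),
             file.path(dir, "families.tsv"))

  ## per-disease target signatures (disjoint) + background noise
  sig_size <- max(1, p$n_targets %/% p$n_diseases)
  sig <- lapply(seq_len(p$n_diseases), function(j)
    seq((j - 1) * sig_size + 1, min(j * sig_size, p$n_targets)))
  target_lines <- character()
  for (i in seq_len(p$n_mirnas)) {
    true_d <- which(A[i, ] == 1)
    tg <- integer()
    for (j in true_d) {
      s <- sig[[j]]
      tg <- c(tg, s[runif(length(s)) < 0.8])
    }
    noise <- which(runif(p$n_targets) < 0.01)
    tg <- sort(unique(c(tg, noise)))
    if (length(tg))
      target_lines <- c(target_lines,
                        sprintf("%s\t%s", mirnas[i], genes[tg]))
  }
  writeLines(c("# mirna\tgene", target_lines), file.path(dir, "targets.tsv"))

  ## abstracts: 80% tokens from the word slices of the miRNA's TRUE
  ## diseases, 20% background
  n_bg <- 40
  slice_size <- (p$n_words - n_bg) %/% p$n_diseases
  word_slice <- lapply(seq_len(p$n_diseases), function(j)
    n_bg + seq((j - 1) * slice_size + 1, j * slice_size))
  bg_pool <- seq_len(n_bg)
  abstract_lines <- character(p$n_mirnas)
  for (i in seq_len(p$n_mirnas)) {
    true_d <- which(A[i, ] == 1)
    pool <- if (length(true_d)) unlist(word_slice[true_d]) else
      unlist(word_slice[which(dis_cl == mir_cl[i])])
    n_tok <- max(20, round(rnorm(1, p$abstract_tokens, p$abstract_tokens / 6)))
    n_sig <- round(0.8 * n_tok)
    toks <- c(sample(pool, n_sig, replace = TRUE),
              sample(bg_pool, n_tok - n_sig, replace = TRUE))
    abstract_lines[i] <- paste(mirnas[i],
                               paste(words[sample(toks)], collapse = " "),
                               sep = "\t")
  }
  writeLines(c("# mirna\ttext", abstract_lines),
             file.path(dir, "abstracts.tsv"))

  jsonlite::write_json(unclass(p), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(true = A, observed = Obs,
                 masked = data.frame(mirna = mirnas[masked[, 1]],
                                     disease = diseases[masked[, 2]],
                                     stringsAsFactors = FALSE),
                 mir_cluster = structure(mir_cl, names = mirnas),
                 dis_cluster = structure(dis_cl, names = diseases)))
}

#' Load the withheld ground-truth associations of a synthetic bundle
#'
#' @param dir bundle directory written by [synth_generate()].
#' @return data.frame with columns `mirna`, `disease`.
#' @export
load_ground_truth <- function(dir) {
  tf <- read_tab_file(file.path(dir, "ground_truth.tsv"))
  data.frame(
    mirna = vapply(tf$fields, `[[`, character(1), 1),
    disease = norm_label(vapply(tf$fields, `[[`, character(1), 2)),
    stringsAsFactors = FALSE)
}

#' The toy miRNA-target bipartite graph of the worked projection example
#'
#' Four miRNAs (a, b, c, d) and four targets (alpha, beta, gamma,
#' delta).  The text-constrained edges are: a targets alpha only; b
#' targets alpha and beta; alpha has degree 2 and beta degree 3.  The
#' attachments of gamma and delta are not constrained by the worked
#' example; this fixture fixes one completion (c targets beta and
#' gamma; d targets beta and delta).  Tests rely only on the
#' text-constrained quantities.
#'
#' @return a binary 4 x 4 matrix with dimnames.
#' @export
fig3_fixture <- function() {
  M <- matrix(0, 4, 4,
              dimnames = list(c("a", "b", "c", "d"),
                              c("alpha", "beta", "gamma", "delta")))
  M["a", "alpha"] <- 1
  M["b", c("alpha", "beta")] <- 1
  M["c", c("beta", "gamma")] <- 1
  M["d", c("beta", "delta")] <- 1
  M
}
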