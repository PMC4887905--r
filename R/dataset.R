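#' A single miRNA record
#'
#' Holds everything known about one (merged) miRNA: genomic locations,
#' family, concatenated literature abstracts, associated diseases and
#' validated targets.  Records produced by different stem-loops of the
#' same mature miRNA are merged with [merge_stem_loops()].
#'
#' Coordinates are 1-based inclusive (GFF3 convention); all distance
#' arithmetic in the package assumes this.
#'
#' @param id canonical miRNA identifier.
#' @param locations data.frame with columns `chrom`, `strand` (`+`/`-`),
#'   `start`, `end` (integers, `start <= end`).
#' @param family family identifier or `NA`.
#' @param abstract_text concatenated abstracts (may be empty).
#' @param diseases character vector of disease ids (deduplicated, sorted).
#' @param targets character vector of target gene ids (deduplicated, sorted).
#' @return an object of class `mirna_record`.
#' @export
mirna_record <- function(id,
                         locations = empty_locations(),
                         family = NA_character_,
                         abstract_text = "",
                         diseases = character(),
                         targets = character()) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  locations <- as.data.frame(locations)
  if (nrow(locations)) {
    if (!all(c("chrom", "strand", "start", "end") %in% names(locations)))
      stop("locations must have columns chrom, strand, start, end")
    if (any(locations$end < locations$start))
      stop("invalid location for ", id, ": end < start")
    if (!all(locations$strand %in% c("+", "-")))
      stop("invalid strand for ", id)
    locations <- locations[order(locations$chrom, locations$start,
                                 locations$end), , drop = FALSE]
    rownames(locations) <- NULL
  }
  structure(
    list(id = id,
         locations = locations,
         family = as.character(family),
         abstract_text = as.character(abstract_text),
         diseases = sort(unique(as.character(diseases))),
         targets = sort(unique(as.character(targets)))),
    class = "mirna_record")
}

empty_locations <- function() {
  data.frame(chrom = character(), strand = character(),
             start = integer(), end = integer())
}

#' @export
print.mirna_record <- function(x, ...) {
  cat("<mirna_record>", x$id, "\n",
      " locations:", nrow(x$locations),
      " family:", ifelse(is.na(x$family), "-", x$family),
      " diseases:", length(x$diseases),
      " targets:", length(x$targets),
      " abstract chars:", nchar(x$abstract_text), "\n")
  invisible(x)
}

#' Assemble a dataset from miRNA records
#'
#' The dataset carries the global, ordered id lists that fix the row and
#' column orderings of every feature block: miRNAs (m), diseases (d),
#' target genes (t), families (f) and the abstract vocabulary (w).
#'
#' @param records list of [mirna_record()] objects with unique ids.
#' @return an object of class `mirna_dataset` with elements `mirnas`
#'   (records sorted by id), `diseases`, `genes`, `families`,
#'   `vocabulary` and the dimension vector `dims`.
#' @export
mirna_dataset <- function(records) {
  stopifnot(is.list(records))
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate miRNA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- records[order(ids)]
  names(records) <- sort(ids)
  diseases <- sort(unique(unlist(lapply(records, `[[`, "diseases"))))
  genes <- sort(unique(unlist(lapply(records, `[[`, "targets"))))
  fams <- vapply(records, `[[`, character(1), "family")
  families <- sort(unique(fams[!is.na(fams)]))
  vocab <- sort(unique(unlist(
    lapply(records, function(r) unique(tokenize(r$abstract_text))))))
  structure(
    list(mirnas = records,
         diseases = as.character(diseases),
         genes = as.character(genes),
         families = as.character(families),
         vocabulary = as.character(vocab),
         dims = c(m = length(records), d = length(diseases),
                  t = length(genes), w = length(vocab),
                  f = length(families))),
    class = "mirna_dataset")
}

#' @export
print.mirna_dataset <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<mirna_dataset> %d miRNAs, %d diseases, %d targets, %d words, %d families\n",
    d["m"], d["d"], d["t"], d["w"], d["f"]))
  cat(sprintf("  associations: %d; located miRNAs: %d\n",
              sum(lengths(lapply(x$mirnas, `[[`, "diseases"))),
              sum(vapply(x$mirnas, function(r) nrow(r$locations) > 0,
                         logical(1)))))
  invisible(x)
}

mirna_ids <- function(dataset) names(dataset$mirnas)

## disease ids associated with each miRNA, as a named list
association_sets <- function(dataset) {
  lapply(dataset$mirnas, `[[`, "diseases")
}
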