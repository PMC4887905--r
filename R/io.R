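#' Load a miRNA-disease association table
#'
#' Expects a TSV with at least two columns, `mirna<TAB>disease`, an
#' optional third `pmid` column, and `#`-comment lines.  Duplicate
#' (mirna, disease) rows are collapsed; disease names are normalized
#' (lowercased, trimmed).  An empty file yields an empty map.
#'
#' @param path path to the TSV file.
#' @param mature_map optional named character vector mapping stem-loop
#'   ids to canonical mature-group ids (applied before deduplication).
#' @return named list: canonical miRNA id -> sorted character vector of
#'   disease ids.
#' @export
load_associations <- function(path, mature_map = NULL) {
  tf <- read_tab_file(path)
  if (!length(tf$fields)) return(structure(list(), names = character()))
  nf <- lengths(tf$fields)
  if (any(nf < 2))
    stop(sprintf("associations file %s, line %d: expected at least 2 tab-separated fields",
                 path, tf$lineno[which(nf < 2)[1]]), call. = FALSE)
  mirna <- trimws(vapply(tf$fields, `[[`, character(1), 1))
  disease <- norm_label(vapply(tf$fields, `[[`, character(1), 2))
  if (!is.null(mature_map)) {
    hit <- mirna %in% names(mature_map)
    mirna[hit] <- unname(mature_map[mirna[hit]])
  }
  lapply(split(disease, mirna), function(d) sort(unique(d)))
}

#' Load miRNA genomic locations from a GFF3 file
#'
#' Parses the GFF3 columns seqid (1), start (4), end (5) and strand (7);
#' the miRNA id is taken from the `Name=` attribute, falling back to
#' `ID=`.  Coordinates are 1-based inclusive.  One miRNA may carry
#' several locations (one per feature line).
#'
#' @param path path to the GFF3 file.
#' @param mature_map optional stem-loop -> mature-group id map.
#' @return named list: miRNA id -> data.frame(chrom, strand, start, end).
#' @export
load_locations <- function(path, mature_map = NULL) {
  tf <- read_tab_file(path)
  if (!length(tf$fields)) return(structure(list(), names = character()))
  out_id <- character(length(tf$fields))
  chrom <- character(length(tf$fields))
  strand <- character(length(tf$fields))
  start <- integer(length(tf$fields))
  end <- integer(length(tf$fields))
  for (k in seq_along(tf$fields)) {
    f <- tf$fields[[k]]
    ln <- tf$lineno[k]
    if (length(f) < 9)
      stop(sprintf("GFF3 file %s, line %d: expected 9 tab-separated columns, got %d",
                   path, ln, length(f)), call. = FALSE)
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop(sprintf("GFF3 file %s, line %d: non-integer coordinates", path, ln),
           call. = FALSE)
    if (e < s)
      stop(sprintf("GFF3 file %s, line %d: end (%d) < start (%d)", path, ln, e, s),
           call. = FALSE)
    if (!f[7] %in% c("+", "-"))
      stop(sprintf("GFF3 file %s, line %d: unknown strand symbol '%s'",
                   path, ln, f[7]), call. = FALSE)
    id <- gff3_attribute(f[9], "Name") %||% gff3_attribute(f[9], "ID")
    if (is.null(id))
      stop(sprintf("GFF3 file %s, line %d: no Name= or ID= attribute", path, ln),
           call. = FALSE)
    out_id[k] <- id; chrom[k] <- f[1]; strand[k] <- f[7]
    start[k] <- s; end[k] <- e
  }
  if (!is.null(mature_map)) {
    hit <- out_id %in% names(mature_map)
    out_id[hit] <- unname(mature_map[out_id[hit]])
  }
  df <- data.frame(chrom = chrom, strand = strand, start = start, end = end)
  lapply(split(df, out_id), function(x) {
    x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
    rownames(x) <- NULL
    x
  })
}

gff3_attribute <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(^|;)\\s*", key, "=([^;]+)"), attrs))[[1]]
  if (length(m) < 3) NULL else trimws(m[3])
}

#' Load a miRNA family table (TSV `mirna<TAB>family`)
#'
#' @param path path to the TSV file.
#' @param mature_map optional stem-loop -> mature-group id map.
#' @return named character vector: miRNA id -> family id.
#' @export
load_families <- function(path, mature_map = NULL) {
  tf <- read_tab_file(path)
  if (!length(tf$fields)) return(structure(character(), names = character()))
  nf <- lengths(tf$fields)
  if (any(nf < 2))
    stop(sprintf("families file %s, line %d: expected 2 tab-separated fields",
                 path, tf$lineno[which(nf < 2)[1]]), call. = FALSE)
  mirna <- trimws(vapply(tf$fields, `[[`, character(1), 1))
  fam <- trimws(vapply(tf$fields, `[[`, character(1), 2))
  if (!is.null(mature_map)) {
    hit <- mirna %in% names(mature_map)
    mirna[hit] <- unname(mature_map[mirna[hit]])
  }
  out <- vapply(split(fam, mirna), function(f) {
    u <- unique(f)
    if (length(u) > 1)
      stop("conflicting families: ", paste(u, collapse = " vs "), call. = FALSE)
    u
  }, character(1))
  out
}

#' Load per-miRNA abstracts
#'
#' Either a directory containing one UTF-8 text file per miRNA (filename
#' = miRNA id) or a single TSV `mirna<TAB>text`.
#'
#' @param path directory or TSV file.
#' @param mature_map optional stem-loop -> mature-group id map; abstracts
#'   of merged members are concatenated.
#' @return named character vector: miRNA id -> text.
#' @export
load_abstracts <- function(path, mature_map = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    mirna <- basename(files)
    text <- vapply(files, function(f)
      paste(readLines(f, warn = FALSE), collapse = " "), character(1))
  } else {
    tf <- read_tab_file(path)
    if (!length(tf$fields)) return(structure(character(), names = character()))
    nf <- lengths(tf$fields)
    if (any(nf < 2))
      stop(sprintf("abstracts file %s, line %d: expected 2 tab-separated fields",
                   path, tf$lineno[which(nf < 2)[1]]), call. = FALSE)
    mirna <- trimws(vapply(tf$fields, `[[`, character(1), 1))
    text <- vapply(tf$fields, function(f)
      paste(f[-1], collapse = " "), character(1))
  }
  if (!is.null(mature_map)) {
    hit <- mirna %in% names(mature_map)
    mirna[hit] <- unname(mature_map[mirna[hit]])
  }
  vapply(split(text, mirna), paste, character(1), collapse = " ")
}

#' Load a miRNA-target table (TSV `mirna<TAB>gene`)
#'
#' @param path path to the TSV file.
#' @param mature_map optional stem-loop -> mature-group id map.
#' @return named list: miRNA id -> sorted character vector of gene ids.
#' @export
load_targets <- function(path, mature_map = NULL) {
  tf <- read_tab_file(path)
  if (!length(tf$fields)) return(structure(list(), names = character()))
  nf <- lengths(tf$fields)
  if (any(nf < 2))
    stop(sprintf("targets file %s, line %d: expected 2 tab-separated fields",
                 path, tf$lineno[which(nf < 2)[1]]), call. = FALSE)
  mirna <- trimws(vapply(tf$fields, `[[`, character(1), 1))
  gene <- trimws(vapply(tf$fields, `[[`, character(1), 2))
  if (!is.null(mature_map)) {
    hit <- mirna %in% names(mature_map)
    mirna[hit] <- unname(mature_map[mirna[hit]])
  }
  lapply(split(gene, mirna), function(g) sort(unique(g)))
}

#' Load a stem-loop to mature-group mapping (TSV `stemloop<TAB>group`)
#'
#' The mature-group table is an explicit input: stem-loop sequences
#' producing the same mature miRNA are merged under the group id.
#'
#' @param path path to the TSV file.
#' @return named character vector: stem-loop id -> canonical group id.
#' @export
load_mature_map <- function(path) {
  tf <- read_tab_file(path)
  if (!length(tf$fields)) return(structure(character(), names = character()))
  nf <- lengths(tf$fields)
  if (any(nf < 2))
    stop(sprintf("mature map %s, line %d: expected 2 tab-separated fields",
                 path, tf$lineno[which(nf < 2)[1]]), call. = FALSE)
  stem <- trimws(vapply(tf$fields, `[[`, character(1), 1))
  grp <- trimws(vapply(tf$fields, `[[`, character(1), 2))
  structure(grp, names = stem)
}

#' Merge stem-loop records into mature-miRNA groups
#'
#' All records mapped to the same canonical id are merged: union of
#' disease and target sets, union of genomic locations, concatenation of
#' abstracts.  The family is taken from any member; members carrying
#' different families raise an explicit conflict error.  Merging is
#' idempotent.
#'
#' @param records list of [mirna_record()] objects.
#' @param mature_map optional named character vector (stem-loop id ->
#'   group id); ids absent from the map are their own group.
#' @return list of merged `mirna_record`s, sorted by id.
#' @export
merge_stem_loops <- function(records, mature_map = NULL) {
  ids <- vapply(records, `[[`, character(1), "id")
  canon <- ids
  if (!is.null(mature_map)) {
    hit <- ids %in% names(mature_map)
    canon[hit] <- unname(mature_map[ids[hit]])
  }
  groups <- split(records, canon)
  merged <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    fams <- unique(vapply(members, `[[`, character(1), "family"))
    fams <- fams[!is.na(fams)]
    if (length(fams) > 1)
      stop("family conflict while merging into '", g, "': ",
           paste(fams, collapse = " vs "), call. = FALSE)
    locs <- do.call(rbind, lapply(members, `[[`, "locations"))
    texts <- vapply(members, `[[`, character(1), "abstract_text")
    texts <- texts[nzchar(texts)]
    mirna_record(
      id = g,
      locations = locs %||% empty_locations(),
      family = if (length(fams)) fams else NA_character_,
      abstract_text = paste(texts, collapse = " "),
      diseases = unlist(lapply(members, `[[`, "diseases")),
      targets = unlist(lapply(members, `[[`, "targets")))
  })
  merged[order(vapply(merged, `[[`, character(1), "id"))]
}

#' Load a complete input bundle into a dataset
#'
#' @param associations,locations,families,abstracts,targets paths to the
#'   corresponding input files (any may be `NULL` to skip that source).
#' @param mature_map optional path to a stem-loop mapping table, or a
#'   named character vector.
#' @return a [mirna_dataset()].
#' @export
load_dataset <- function(associations = NULL, locations = NULL,
                         families = NULL, abstracts = NULL,
                         targets = NULL, mature_map = NULL) {
  if (is.character(mature_map) && length(mature_map) == 1 &&
      file.exists(mature_map))
    mature_map <- load_mature_map(mature_map)
  assoc <- if (is.null(associations)) list() else
    load_associations(associations, mature_map)
  locs <- if (is.null(locations)) list() else
    load_locations(locations, mature_map)
  fams <- if (is.null(families)) character() else
    load_families(families, mature_map)
  texts <- if (is.null(abstracts)) character() else
    load_abstracts(abstracts, mature_map)
  targ <- if (is.null(targets)) list() else
    load_targets(targets, mature_map)
  ids <- sort(unique(c(names(assoc), names(locs), names(fams),
                       names(texts), names(targ))))
  records <- lapply(ids, function(id) {
    mirna_record(
      id = id,
      locations = locs[[id]] %||% empty_locations(),
      family = if (id %in% names(fams)) fams[[id]] else NA_character_,
      abstract_text = if (id %in% names(texts)) texts[[id]] else "",
      diseases = assoc[[id]] %||% character(),
      targets = targ[[id]] %||% character())
  })
  mirna_dataset(records)
}

#' Load a bundle directory with the standard file layout
#'
#' Looks for `associations.tsv`, `locations.gff3`, `families.tsv`,
#' `abstracts.tsv`, `targets.tsv` and optionally `mature_map.tsv` in
#' `dir` (missing files are skipped).  The disease tree
#' (`mesh_tree.tsv`) is loaded separately with [build_ontology()].
#'
#' @param dir bundle directory.
#' @return a [mirna_dataset()].
#' @export
load_bundle <- function(dir) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (file.exists(fp)) fp else NULL
  }
  load_dataset(associations = p("associations.tsv"),
               locations = p("locations.gff3"),
               families = p("families.tsv"),
               abstracts = p("abstracts.tsv"),
               targets = p("targets.tsv"),
               mature_map = p("mature_map.tsv"))
}

#' Write a dataset back to the bundle formats
#'
#' Produces the same five files that [load_bundle()] reads, so that a
#' write/load round trip reproduces the dataset exactly.
#'
#' @param dataset a [mirna_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- dataset$mirnas
  assoc <- unlist(lapply(recs, function(r)
    if (length(r$diseases)) paste(r$id, r$diseases, sep = "\t")), use.names = FALSE)
  writeLines(c("# mirna\tdisease", assoc %||% character()),
             file.path(dir, "associations.tsv"))
  gff <- unlist(lapply(recs, function(r) {
    if (!nrow(r$locations)) return(NULL)
    sprintf("%s\tmirlsa\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
            r$locations$chrom, r$locations$start, r$locations$end,
            r$locations$strand, r$id, r$id)
  }), use.names = FALSE)
  writeLines(c("##gff-version 3", gff %||% character()),
             file.path(dir, "locations.gff3"))
  fams <- unlist(lapply(recs, function(r)
    if (!is.na(r$family)) paste(r$id, r$family, sep = "\t")), use.names = FALSE)
  writeLines(c("# mirna\tfamily", fams %||% character()),
             file.path(dir, "families.tsv"))
  texts <- unlist(lapply(recs, function(r)
    if (nzchar(r$abstract_text)) paste(r$id, r$abstract_text, sep = "\t")),
    use.names = FALSE)
  writeLines(c("# mirna\ttext", texts %||% character()),
             file.path(dir, "abstracts.tsv"))
  targ <- unlist(lapply(recs, function(r)
    if (length(r$targets)) paste(r$id, r$targets, sep = "\t")), use.names = FALSE)
  writeLines(c("# mirna\tgene", targ %||% character()),
             file.path(dir, "targets.tsv"))
  invisible(dir)
}
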