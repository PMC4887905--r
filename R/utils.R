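#' @importFrom methods as is new
#' @importFrom stats rbinom rnorm runif
#' @importFrom utils head tail write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a disease or term label
#'
#' Labels are matched across the association table and the ontology tree
#' file by exact string equality after lowercasing and trimming
#' surrounding whitespace.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
norm_label <- function(x) tolower(trimws(x))

## Evaluate `code` under a fixed seed without disturbing the caller's RNG
## stream.  All randomness in the package flows through this helper.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Read a tab-separated text file, skipping '#' comments and blank lines.
## Returns the split fields together with original line numbers so that
## format errors can name the offending line.
read_tab_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' English stop words used by the abstract tokenizer
#'
#' A small fixed list of frequent function words dropped before TF-IDF
#' weighting.
#'
#' @return character vector of stop words.
#' @export
mirlsa_stopwords <- function() {
  c("the", "and", "for", "are", "was", "were", "with", "that", "this",
    "from", "have", "has", "had", "not", "but", "all", "can", "been",
    "its", "also", "which", "into", "than", "then", "them", "they",
    "their", "there", "these", "those", "such", "when", "where", "while",
    "who", "whom", "why", "how", "what", "our", "out", "over", "under",
    "between", "both", "each", "few", "more", "most", "other", "some",
    "any", "only", "own", "same", "too", "very", "just", "may", "might",
    "must", "shall", "should", "will", "would", "could", "did", "does",
    "doing", "done", "being", "because", "before", "after", "above",
    "below", "during", "through", "about", "against", "among", "within",
    "without", "upon", "per", "via", "using", "used", "use", "one",
    "two", "three", "however", "therefore", "thus", "here", "found",
    "show", "shown", "showed", "study", "studies", "result", "results")
}

#' Tokenize free text for the word feature block
#'
#' Lowercases, extracts runs of alphabetic characters, keeps tokens of at
#' least `min_chars` characters, and removes stop words.
#'
#' @param text character scalar (a document).
#' @param min_chars minimum token length (default 3).
#' @param stopwords character vector of words to drop.
#' @return character vector of tokens (with repetitions).
#' @export
tokenize <- function(text, min_chars = 3, stopwords = mirlsa_stopwords()) {
  if (length(text) == 0 || is.na(text) || !nzchar(text)) return(character())
  toks <- regmatches(text, gregexpr("[a-z]+", tolower(text)))[[1]]
  toks <- toks[nchar(toks) >= min_chars]
  toks[!(toks %in% stopwords)]
}
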