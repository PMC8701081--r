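#' Tokenize and lemmatize one abstract
#'
#' Lowercases the text, strips punctuation and numbers, lemmatizes each
#' remaining token (lexicon lookup backed by English plural-stripping
#' rules), and removes stop-listed lemmas. The stop list is applied after
#' lemmatization, so listing `"method"` also removes `"methods"`.
#'
#' @param abstract A single character string.
#' @param stop_list Character vector of lemmas to drop; defaults to the
#'   shipped list ([default_stop_list()]), which combines common English
#'   stopwords with scientific boilerplate ("introduction", "method", ...).
#' @param lexicon Named character vector mapping inflected forms to lemmas;
#'   defaults to the shipped lexicon.
#' @return Character vector of lemmas (possibly empty).
#' @examples
#' tokenize_and_lemmatize("The methods of viruses")
#' @export
tokenize_and_lemmatize <- function(abstract,
                                   stop_list = default_stop_list(),
                                   lexicon = default_lemma_lexicon()) {
  stopifnot(is.character(abstract), length(abstract) == 1)
  toks <- strsplit(tolower(abstract), "[^a-z]+")[[1]]
  toks <- toks[nchar(toks) >= 2]
  if (length(toks) == 0) return(character(0))
  lemmas <- lemmatize_tokens(toks, lexicon)
  lemmas[!(lemmas %in% stop_list)]
}

#' Tokenize every abstract in a record table
#'
#' @param records Tibble with `doc_id` and `abstract` columns.
#' @inheritParams tokenize_and_lemmatize
#' @return A tibble with columns `doc_id`, `tokens` (list-column of lemma
#'   vectors) and `n_tokens`. Documents reduced to zero tokens are kept
#'   here (with `n_tokens = 0`) and dropped, with a report, by
#'   [build_tfidf()].
#' @export
tokenize_abstracts <- function(records,
                               stop_list = default_stop_list(),
                               lexicon = default_lemma_lexicon()) {
  tokens <- lapply(records$abstract, tokenize_and_lemmatize,
                   stop_list = stop_list, lexicon = lexicon)
  tibble::tibble(
    doc_id = records$doc_id,
    tokens = tokens,
    n_tokens = lengths(tokens)
  )
}

# Lexicon lookup first; otherwise conservative plural stripping.
lemmatize_tokens <- function(tokens, lexicon) {
  out <- unname(lexicon[tokens])
  miss <- is.na(out)
  out[miss] <- vapply(tokens[miss], strip_plural, character(1),
                      USE.NAMES = FALSE)
  out
}

# Plural rules only: -ies -> -y; -es stripped when the stem ends in a
# sibilant cluster that takes -es (viruses -> virus, classes -> class)
# else just -s (diseases -> disease); trailing -s stripped unless the
# word ends -ss/-us/-is.
strip_plural <- function(w) {
  n <- nchar(w)
  if (n > 4 && endsWith(w, "ies")) {
    return(paste0(substr(w, 1, n - 3), "y"))
  }
  if (n > 4 && endsWith(w, "es")) {
    stem <- substr(w, 1, n - 2)
    if (grepl("(x|z|ch|sh|ss|us|is)$", stem)) return(stem)
  }
  if (n > 3 && endsWith(w, "s") &&
      !grepl("(ss|us|is)$", w)) {
    return(substr(w, 1, n - 1))
  }
  w
}

the_litprior_env <- new.env(parent = emptyenv())

#' Shipped stop list
#'
#' Common English stopwords plus boilerplate terms of scientific prose.
#' Stored one lemma per line in `inst/extdata/stopwords.txt`; users can
#' supply their own vector to the tokenizer instead.
#' @return Character vector of stop lemmas.
#' @export
default_stop_list <- function() {
  if (is.null(the_litprior_env$stop_list)) {
    path <- system.file("extdata", "stopwords.txt", package = "litprior")
    the_litprior_env$stop_list <- readLines(path, warn = FALSE)
  }
  the_litprior_env$stop_list
}

#' Shipped lemma lexicon
#'
#' Irregular and domain-frequent inflected forms mapped to lemmas, stored
#' as two whitespace-separated columns in `inst/extdata/lemma-lexicon.txt`.
#' Regular plurals are handled by rules and need not be listed.
#' @return Named character vector (names = inflected form, value = lemma).
#' @export
default_lemma_lexicon <- function() {
  if (is.null(the_litprior_env$lexicon)) {
    path <- system.file("extdata", "lemma-lexicon.txt", package = "litprior")
    tab <- utils::read.table(path, header = FALSE, col.names = c("form", "lemma"),
                             stringsAsFactors = FALSE)
    the_litprior_env$lexicon <- stats::setNames(tab$lemma, tab$form)
  }
  the_litprior_env$lexicon
}

#' Build a pruned vocabulary from tokenized documents
#'
#' Retains exactly the lemmas whose total occurrence count is at least
#' `min_abs_freq` and whose document frequency is at most
#' `max_rel_df * n_docs`, in lexicographic order.
#'
#' @param token_docs List of lemma vectors, or the tibble from
#'   [tokenize_abstracts()].
#' @param min_abs_freq Minimum total occurrences to retain a lemma.
#' @param max_rel_df Maximum document-frequency fraction to retain a lemma
#'   (prunes near-ubiquitous terms).
#' @return A tibble of class `lit_vocabulary` with columns `lemma`,
#'   `abs_freq`, `doc_freq`, and attribute `n_docs`.
#' @export
build_vocabulary <- function(token_docs, min_abs_freq = 4, max_rel_df = 0.8) {
  token_docs <- as_token_list(token_docs)
  n_docs <- length(token_docs)
  if (n_docs == 0 || all(lengths(token_docs) == 0)) {
    stop("need at least one non-empty tokenized document", call. = FALSE)
  }
  abs_tab <- table(unlist(token_docs, use.names = FALSE))
  df_tab <- table(unlist(lapply(token_docs, unique), use.names = FALSE))
  lemmas <- sort(names(abs_tab), method = "radix")
  abs_freq <- as.integer(abs_tab[lemmas])
  doc_freq <- as.integer(df_tab[lemmas])
  keep <- abs_freq >= min_abs_freq & doc_freq <= max_rel_df * n_docs
  if (!any(keep)) {
    stop("vocabulary is empty after pruning; lower min_abs_freq or raise ",
         "max_rel_df", call. = FALSE)
  }
  out <- tibble::tibble(
    lemma = lemmas[keep], abs_freq = abs_freq[keep], doc_freq = doc_freq[keep]
  )
  attr(out, "n_docs") <- n_docs
  attr(out, "min_abs_freq") <- min_abs_freq
  attr(out, "max_rel_df") <- max_rel_df
  class(out) <- c("lit_vocabulary", class(out))
  out
}

as_token_list <- function(token_docs) {
  if (is.data.frame(token_docs)) {
    stats::setNames(token_docs$tokens, token_docs$doc_id)
  } else {
    token_docs
  }
}

#' Build the TF-IDF document-term matrix
#'
#' Entry (i, j) is `tf(i, j) * ln(n / df(j))` with `tf` the raw count of
#' lemma j in document i and `df` its document frequency among the `n`
#' input documents. No row normalization is applied; near-ubiquitous terms
#' (zero or near-zero idf) are expected to have been pruned by
#' [build_vocabulary()]. Documents with an all-zero row (no retained
#' lemmas) are dropped and counted in the attached report.
#'
#' @param token_docs List of lemma vectors (optionally named by doc id), or
#'   the tibble from [tokenize_abstracts()].
#' @param vocab A [build_vocabulary()] result built from the same documents.
#' @return An object of class `term_matrix`: list with `values` (sparse
#'   `dgCMatrix`, documents x lemmas), `row_ids`, `vocabulary`, and a
#'   `report` listing dropped documents.
#' @export
build_tfidf <- function(token_docs, vocab) {
  token_docs <- as_token_list(token_docs)
  n <- length(token_docs)
  ids <- names(token_docs)
  if (is.null(ids)) ids <- sprintf("doc%05d", seq_len(n))
  m <- nrow(vocab)

  triplets <- purrr::imap(token_docs, function(toks, i) {
    j <- match(toks, vocab$lemma)
    j <- j[!is.na(j)]
    if (length(j) == 0) return(NULL)
    cnt <- table(j)
    list(j = as.integer(names(cnt)), x = as.numeric(cnt))
  })
  # df over the input corpus (vocab carries it, built from the same docs)
  idf <- log(n / vocab$doc_freq)

  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_len(n)) {
    tr <- triplets[[i]]
    if (is.null(tr)) next
    rows <- c(rows, rep.int(i, length(tr$j)))
    cols <- c(cols, tr$j)
    vals <- c(vals, tr$x * idf[tr$j])
  }
  values <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                 dims = c(n, m),
                                 dimnames = list(ids, vocab$lemma))
  nonzero_row <- Matrix::rowSums(values != 0) > 0
  dropped <- ids[!nonzero_row]
  values <- values[nonzero_row, , drop = FALSE]

  structure(
    list(values = values, row_ids = ids[nonzero_row], vocabulary = vocab,
         report = list(n_in = n, n_kept = sum(nonzero_row),
                       dropped_empty_rows = dropped)),
    class = "term_matrix"
  )
}

#' @exportS3Method base::print
print.term_matrix <- function(x, ...) {
  cat("<term_matrix> ", nrow(x$values), " documents x ", ncol(x$values),
      " lemmas (TF-IDF, ",
      format(Matrix::nnzero(x$values), big.mark = ","), " nonzeros)\n",
      sep = "")
  invisible(x)
}

#' @export
dim.term_matrix <- function(x) dim(x$values)

#' Export a term matrix as Matrix Market + lemma sidecar
#'
#' Writes `values` in MTX sparse format to `path` and the vocabulary
#' lemmas, one per line, to `paste0(path, ".lemmas")`.
#'
#' @param x A `term_matrix`.
#' @param path Output path for the MTX file.
#' @return `path`, invisibly.
#' @export
write_term_matrix <- function(x, path) {
  stopifnot(inherits(x, "term_matrix"))
  Matrix::writeMM(x$values, path)
  writeLines(x$vocabulary$lemma, paste0(path, ".lemmas"))
  invisible(path)
}
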