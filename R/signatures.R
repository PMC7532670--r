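# Slide-level pathological signatures: the 200-dimensional feature vector
# FEA#001..FEA#200 = 100 patch-likelihood histogram bins (PALHI block)
# followed by 100 TF-IDF likelihood-word weights (BoW block).

#' Patch-likelihood histogram (PALHI block)
#'
#' Represents a slide by the occurrence histogram of its patch MSI
#' likelihoods over `n_bins` equal-width bins on `[0, 1]` (bin i covers
#' `[(i-1)/n, i/n)`, the last bin closed), normalised to sum to 1.
#'
#' @param likelihoods Numeric bag of patch likelihoods in `[0, 1]`.
#' @param n_bins Number of bins (default 100).
#' @return Numeric vector of bin frequencies summing to 1.
#' @export
palhi_histogram <- function(likelihoods, n_bins = 100L) {
  if (length(likelihoods) == 0) stop_pathomsi("empty likelihood bag")
  if (any(likelihoods < 0 | likelihoods > 1)) {
    stop_pathomsi("likelihoods must lie in [0, 1]")
  }
  bin <- pmin(floor(likelihoods * n_bins) + 1L, n_bins)
  tabulate(bin, nbins = n_bins) / length(likelihoods)
}

#' Likelihood word of a patch
#'
#' Uniform quantisation of a likelihood into one of `n_words` vocabulary
#' words: `ceiling(n * p)` clamped to `[1, n]` (so `p = 0` maps to word 1).
#'
#' @param p Likelihoods in `[0, 1]`.
#' @param n_words Vocabulary size (default 100).
#' @return Integer word indices.
#' @export
likelihood_word <- function(p, n_words = 100L) {
  pmax(1L, pmin(as.integer(ceiling(p * n_words)), n_words))
}

#' Fit the bag-of-words vocabulary (smoothed IDF)
#'
#' Document frequency `df(w)` counts the slides whose bag contains word `w`;
#' the smoothed inverse document frequency is
#' `idf(w) = ln((1 + N) / (1 + df(w))) + 1` with `N` the number of slides,
#' finite and positive even for unseen words.
#'
#' @param likelihood_table Patch-likelihood tibble (`slide_id`, `likelihood`)
#'   or a list of likelihood bags.
#' @param n_words Vocabulary size (default 100).
#' @return A `bow_vocabulary` with `idf`, `n_words`, `n_slides_fit`.
#' @export
fit_bow_vocabulary <- function(likelihood_table, n_words = 100L) {
  bags <- as_bags(likelihood_table)
  if (length(bags) < 1) stop_pathomsi("need at least one slide to fit a vocabulary")
  df <- integer(n_words)
  for (bag in bags) {
    w <- unique(likelihood_word(bag, n_words))
    df[w] <- df[w] + 1L
  }
  n <- length(bags)
  structure(list(idf = log((1 + n) / (1 + df)) + 1, n_words = as.integer(n_words),
                 n_slides_fit = n),
            class = "bow_vocabulary")
}

#' @export
print.bow_vocabulary <- function(x, ...) {
  cat("<bow_vocabulary>", x$n_words, "words, fitted on", x$n_slides_fit, "slides\n")
  invisible(x)
}

as_bags <- function(x) {
  if (is.list(x) && !is.data.frame(x)) return(x)
  split(x$likelihood, x$slide_id)
}

#' TF-IDF vector of one slide (BoW block)
#'
#' Term frequency `tf(w)` is the fraction of the slide's patches mapping to
#' word `w`; the block is `tf * idf`, L2-normalised. Duplicating every patch
#' leaves the vector unchanged.
#'
#' @param likelihoods Numeric bag of patch likelihoods.
#' @param vocab A [fit_bow_vocabulary()] result.
#' @return Numeric vector of length `vocab$n_words` with unit L2 norm.
#' @export
tfidf_vector <- function(likelihoods, vocab) {
  if (length(likelihoods) == 0) stop_pathomsi("empty likelihood bag")
  w <- likelihood_word(likelihoods, vocab$n_words)
  tf <- tabulate(w, nbins = vocab$n_words) / length(likelihoods)
  v <- tf * vocab$idf
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Build the slide-by-signature matrix
#'
#' One row per slide: `FEA#001`..`FEA#100` the PALHI histogram, `FEA#101`..
#' `FEA#200` the BoW TF-IDF weights.
#'
#' @param likelihood_table Patch-likelihood tibble (`slide_id`, `likelihood`).
#' @param vocab A fitted `bow_vocabulary`.
#' @param n_bins Histogram bins (default 100).
#' @return A tibble with `slide_id` and the 200 `FEA#` columns.
#' @export
build_signatures <- function(likelihood_table, vocab, n_bins = 100L) {
  bags <- as_bags(likelihood_table)
  mat <- t(vapply(bags, function(bag) {
    c(palhi_histogram(bag, n_bins), tfidf_vector(bag, vocab))
  }, numeric(n_bins + vocab$n_words)))
  colnames(mat) <- fea_names(n_bins, vocab$n_words)
  dplyr::bind_cols(tibble(slide_id = names(bags)), as_tibble(mat))
}

signature_matrix <- function(signatures) {
  as.matrix(signatures[, grep("^FEA#", names(signatures)), drop = FALSE])
}

#' Write / read a signature matrix TSV
#'
#' @param signatures Tibble from [build_signatures()].
#' @param path TSV path (rows = slides, columns `FEA#001`..).
#' @return `path` / the tibble.
#' @export
write_signatures <- function(signatures, path) {
  utils::write.table(signatures, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE,
                              comment.char = ""))  # '#' is part of FEA names
}
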