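# Internal helpers shared across modules.

stop_pathomsi <- function(msg, class = "pathomsi_error") {
  rlang::abort(msg, class = class)
}

# Binary slide labels are stored as character "MSI"/"MSS"; 1/0 internally.
ms_label_levels <- c("MSS", "MSI")

as_label01 <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop_pathomsi("numeric labels must be 0/1 (1 = MSI)")
    }
    return(as.integer(labels))
  }
  if (!all(labels %in% ms_label_levels)) {
    stop_pathomsi("labels must be 'MSI' or 'MSS'")
  }
  as.integer(labels == "MSI")
}

label_chr <- function(label01) ifelse(label01 == 1, "MSI", "MSS")

check_both_classes <- function(label01, what = "training set") {
  if (length(unique(label01)) < 2) {
    stop_pathomsi(paste0("single-class ", what, ": both MSI and MSS are required"))
  }
  invisible(label01)
}

# Deterministic seeded evaluation that does not disturb the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# FEA#001 ... FEA#200 layout: 100 histogram bins then 100 TF-IDF words.
fea_names <- function(n_bins = 100L, n_words = 100L) {
  sprintf("FEA#%03d", seq_len(n_bins + n_words))
}
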