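# Genomic and transcriptomic association quantities: TMB, INDEL load,
# pathway deficiency calls, 0-1 normalisation, CYT and CD8 T-effector
# scores, Spearman correlation.

#' Gene sets used in the association analyses
#'
#' `mmr_genes`: the mismatch-repair pathway; `cyt_genes`: the cytolytic
#' activity pair; `cd8_t_effector_genes`: the CD8+ T-effector set.
#' @name gene_sets
#' @export
mmr_genes <- c("MLH1", "MSH2", "MSH6", "PMS2")

#' @rdname gene_sets
#' @export
cyt_genes <- c("GZMA", "PRF1")

#' @rdname gene_sets
#' @export
cd8_t_effector_genes <- c("CD8A", "IFNG", "GZMA", "PRF1", "CXCL9", "CXCL10",
                          "TBX21", "GZMB")

# Controlled variant-class vocabulary; synonymous is excluded downstream.
variant_classes <- c("missense", "nonsense", "frameshift", "INS", "DEL",
                     "splice", "nonstop", "start_lost", "synonymous")

# MAF Variant_Classification -> controlled vocabulary.
maf_class_map <- c(
  "Missense_Mutation" = "missense", "Nonsense_Mutation" = "nonsense",
  "Frame_Shift_Ins" = "INS", "Frame_Shift_Del" = "DEL",
  "In_Frame_Ins" = "INS", "In_Frame_Del" = "DEL",
  "Splice_Site" = "splice", "Nonstop_Mutation" = "nonstop",
  "Translation_Start_Site" = "start_lost", "Silent" = "synonymous"
)

#' Construct a mutation profile
#'
#' Normalises a per-variant table to the controlled vocabulary. Accepts
#' either already-normalised columns (`sample_id`, `gene`, `variant_class`)
#' or MAF-style columns (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`, mapped via the documented synonym table).
#'
#' @param df Variant table.
#' @param exome_size_mb Exome size in megabases used as the TMB divisor
#'   (default 38).
#' @return A `mutation_profile` tibble with attribute `exome_size_mb`.
#' @export
mutation_profile <- function(df, exome_size_mb = 38) {
  df <- as_tibble(df)
  if ("Tumor_Sample_Barcode" %in% names(df)) df$sample_id <- df$Tumor_Sample_Barcode
  if ("Hugo_Symbol" %in% names(df)) df$gene <- df$Hugo_Symbol
  if ("Variant_Classification" %in% names(df)) {
    cls <- maf_class_map[df$Variant_Classification]
    if (any(is.na(cls))) {
      bad <- unique(df$Variant_Classification[is.na(cls)])
      stop_pathomsi(paste0("unknown Variant_Classification: ",
                           paste(bad, collapse = ", ")))
    }
    df$variant_class <- unname(cls)
  }
  need <- c("sample_id", "gene", "variant_class")
  if (!all(need %in% names(df))) {
    stop_pathomsi("mutation profile needs sample_id, gene, variant_class columns")
  }
  if (!all(df$variant_class %in% variant_classes)) {
    bad <- setdiff(unique(df$variant_class), variant_classes)
    stop_pathomsi(paste0("variant_class outside the controlled vocabulary: ",
                         paste(bad, collapse = ", ")))
  }
  out <- df[, need]
  attr(out, "exome_size_mb") <- exome_size_mb
  class(out) <- c("mutation_profile", class(out))
  out
}

#' Read a MAF-like TSV as a mutation profile
#'
#' @param path TSV path.
#' @inheritParams mutation_profile
#' @export
read_mutation_profile <- function(path, exome_size_mb = 38) {
  mutation_profile(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE, quote = "\""),
                   exome_size_mb = exome_size_mb)
}

profile_sample <- function(profile, sample_id) {
  if (!sample_id %in% profile$sample_id) {
    stop_pathomsi(paste0("unknown sample: ", sample_id))
  }
  profile[profile$sample_id == sample_id, ]
}

#' Tumour mutation burden
#'
#' Count of somatic nonsynonymous variant rows (every controlled class except
#' `synonymous`, so insertions and deletions count) divided by the exome size
#' in megabases.
#'
#' @param profile A [mutation_profile()].
#' @param sample_id Sample to score.
#' @return Mutations per megabase.
#' @export
tmb <- function(profile, sample_id) {
  rows <- profile_sample(profile, sample_id)
  sum(rows$variant_class != "synonymous") / attr(profile, "exome_size_mb")
}

#' INDEL mutation load
#'
#' Count of insertion (`INS`) and deletion (`DEL`) variant rows for a sample;
#' duplicate rows count separately.
#'
#' @inheritParams tmb
#' @return Integer count.
#' @export
indel_load <- function(profile, sample_id) {
  rows <- profile_sample(profile, sample_id)
  sum(rows$variant_class %in% c("INS", "DEL"))
}

#' Pathway deficiency call
#'
#' A sample is `"deficient"` for a gene set as soon as any nonsynonymous
#' variant hits any member gene, else `"proficient"`.
#'
#' @inheritParams tmb
#' @param gene_set Non-empty character vector of member genes.
#' @return `"deficient"` or `"proficient"`.
#' @export
pathway_deficiency <- function(profile, sample_id, gene_set = mmr_genes) {
  if (length(gene_set) == 0) stop_pathomsi("empty gene set")
  # a sample without any variant row is trivially proficient
  rows <- profile[profile$sample_id == sample_id, ]
  hit <- any(rows$gene %in% gene_set & rows$variant_class != "synonymous")
  if (hit) "deficient" else "proficient"
}

#' Min-max normalisation to [0, 1]
#'
#' `(x - min) / (max - min)`; an all-equal input maps to all 0.5 with a
#' warning. Idempotent on non-degenerate already-normalised input.
#'
#' @param values Numeric vector (length >= 1).
#' @return Normalised vector.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 1) stop_pathomsi("need at least one value")
  rng <- range(values)
  if (diff(rng) == 0) {
    rlang::warn("constant input to minmax_normalize; returning 0.5")
    return(rep(0.5, length(values)))
  }
  (values - rng[1]) / diff(rng)
}

expr_value <- function(expr, gene, sample_id) {
  if (!sample_id %in% colnames(expr)) stop_pathomsi(paste0("unknown sample: ", sample_id))
  expr[gene, sample_id]
}

#' Cytolytic activity (CYT) score
#'
#' Geometric mean of GZMA and PRF1 expression with a pseudocount of 1 so
#' zero expression is tolerated: `sqrt((GZMA + 1) * (PRF1 + 1)) - 1`.
#'
#' @param expr Nonnegative expression matrix, genes as rownames, samples as
#'   column names.
#' @param sample_id Sample to score.
#' @return The CYT score.
#' @export
cyt_score <- function(expr, sample_id) {
  for (g in cyt_genes) {
    if (!g %in% rownames(expr)) stop_pathomsi(paste0("missing gene: ", g))
  }
  sqrt(prod(expr_value(expr, cyt_genes, sample_id) + 1)) - 1
}

#' Mean log2 gene-set score
#'
#' Mean of `log2(x + 1)` over the member genes present in the matrix
#' (defaults to the CD8+ T-effector set); warns about missing members,
#' errors when none are present.
#'
#' @inheritParams cyt_score
#' @param genes Gene set (default [cd8_t_effector_genes]).
#' @return The mean log2 expression score.
#' @export
gene_set_score <- function(expr, sample_id, genes = cd8_t_effector_genes) {
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) {
    stop_pathomsi("none of the gene-set members are present in the matrix")
  }
  if (length(present) < length(genes)) {
    rlang::warn(paste0(length(genes) - length(present), " missing gene(s) in set"))
  }
  mean(log2(expr_value(expr, present, sample_id) + 1))
}

#' Read an expression matrix TSV (genes x samples)
#'
#' @param path TSV with gene identifiers in the first column and sample IDs
#'   in the header.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks; two-sided p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Constant input yields `NA` with a warning.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return A list `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop_pathomsi("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_pathomsi("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::warn("constant input to spearman_corr")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}
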