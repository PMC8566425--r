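# Transcriptional immune-signature scoring on log2 expression matrices:
# probe collapse by maximum average expression, per-gene z-scaling, mean
# member-gene scores, and young-vs-old Wilcoxon rank-sum tests with
# Holm-Bonferroni correction across signatures.

#' Expression generator specification
#'
#' Emulates the structure of a quantile-normalized log2 microarray study of
#' reduction mammoplasty tissue: 121 samples with ages spanning young
#' (<= 35 y, n = 51), intermediate, and older (>= 50 y, n = 23) groups, with
#' 1 or more probes per gene and additive group shifts applied to signature
#' member genes only.
#'
#' @param n_genes gene universe size.
#' @param max_probes_per_gene probes per gene drawn uniformly from
#'   1..max.
#' @param n_young,n_old,n_mid samples per age group.
#' @param effects named numeric: per signature, shift of the older group in
#'   sd units (positive = up with age).
#' @param noise_sd residual sd of expression values.
#' @param seed integer seed.
#' @return object of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 1000L, max_probes_per_gene = 3L,
                            n_young = 51L, n_old = 23L, n_mid = 47L,
                            effects = c(), noise_sd = 1, seed = 1L) {
  if (n_young < 2L || n_old < 2L) stop("group sizes must be >= 2")
  if (length(effects) && any(!is.finite(effects))) stop("shifts must be finite")
  structure(list(n_genes = as.integer(n_genes),
                 max_probes_per_gene = as.integer(max_probes_per_gene),
                 n_young = as.integer(n_young), n_old = as.integer(n_old),
                 n_mid = as.integer(n_mid), effects = effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate a probe-level expression matrix with signature structure
#'
#' @param spec an [expression_spec()].
#' @param signatures named list of gene-identifier vectors; every member
#'   gene must exist in the `g0001..gN` universe.
#' @return list: `expr` (probes x samples), `probe_gene` (data.frame
#'   `probe_id`, `gene`), `ages` (per sample), `groups` (young/mid/old).
#' @export
generate_expression <- function(spec, signatures = list()) {
  stopifnot(inherits(spec, "expression_spec"))
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  missing <- setdiff(unique(unlist(signatures)), genes)
  if (length(missing))
    stop("signature references unknown genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  with_seed(spec$seed, {
    nprobe <- sample.int(spec$max_probes_per_gene, spec$n_genes, TRUE)
    probe_gene <- data.frame(
      probe_id = sprintf("p%05d", seq_len(sum(nprobe))),
      gene = rep(genes, nprobe))
    n_samp <- spec$n_young + spec$n_mid + spec$n_old
    groups <- c(rep("young", spec$n_young), rep("mid", spec$n_mid),
                rep("old", spec$n_old))
    ages <- c(stats::runif(spec$n_young, 24, 35),
              stats::runif(spec$n_mid, 36, 49),
              stats::runif(spec$n_old, 50, 74))
    ord <- sample.int(n_samp)        # shuffle column order
    groups <- groups[ord]; ages <- ages[ord]

    gene_mu <- stats::setNames(stats::rnorm(spec$n_genes, 7, 1.5), genes)
    probe_off <- stats::rnorm(nrow(probe_gene), 0, 0.5)
    shift <- stats::setNames(numeric(spec$n_genes), genes)
    for (sig in names(spec$effects))
      shift[signatures[[sig]]] <- shift[signatures[[sig]]] +
        spec$effects[[sig]] * spec$noise_sd
    expr <- matrix(stats::rnorm(nrow(probe_gene) * n_samp, 0, spec$noise_sd),
                   nrow(probe_gene), n_samp)
    expr <- expr + gene_mu[probe_gene$gene] + probe_off
    old_cols <- which(groups == "old")
    expr[, old_cols] <- expr[, old_cols] + shift[probe_gene$gene]
    rownames(expr) <- probe_gene$probe_id
    colnames(expr) <- sprintf("S%03d", seq_len(n_samp))
    list(expr = expr, probe_gene = probe_gene, ages = ages, groups = groups)
  })
}

#' Read gene signatures from a GMT file
#'
#' Uses `fgsea::gmtPathways()` when available, else a plain parser of the
#' tab-separated GMT layout (name, description, genes...).
#'
#' @param path GMT file.
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1L))
}

#' Write gene signatures to a GMT file
#'
#' @param signatures named list of gene vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @return invisibly, `path`.
#' @export
write_gmt <- function(signatures, path, description = "synthetic") {
  lines <- vapply(names(signatures), function(nm)
    paste(c(nm, description, signatures[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Collapse probes to genes by maximum average expression
#'
#' Per gene, keeps the single probe whose mean across all samples is
#' maximal; ties break by probe identifier order. Probes without annotation
#' are dropped (count reported as an attribute).
#'
#' @param expr probes x samples matrix with probe rownames.
#' @param annotation data.frame `probe_id`, `gene`.
#' @return genes x samples matrix; attribute `n_unannotated`.
#' @export
collapse_probes <- function(expr, annotation) {
  if (!nrow(expr)) stop("empty expression matrix")
  ann <- annotation[match(rownames(expr), annotation$probe_id), ]
  drop <- is.na(ann$gene)
  expr2 <- expr[!drop, , drop = FALSE]
  ann <- ann[!drop, , drop = FALSE]
  means <- rowMeans(expr2)
  ord <- order(ann$gene, -means, ann$probe_id)
  keep <- ord[!duplicated(ann$gene[ord])]
  out <- expr2[keep, , drop = FALSE]
  rownames(out) <- ann$gene[keep]
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "n_unannotated") <- sum(drop)
  out
}

#' Scale genes to zero mean and unit variance across samples
#'
#' Zero-variance genes are dropped with a warning.
#'
#' @param gene_matrix genes x samples matrix.
#' @return scaled matrix.
#' @export
scale_genes <- function(gene_matrix) {
  sds <- apply(gene_matrix, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance genes dropped")
    gene_matrix <- gene_matrix[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (gene_matrix - rowMeans(gene_matrix)) / sds
}

#' Score signatures per sample
#'
#' Score = mean of the scaled values of the signature's member genes present
#' in the matrix. Signatures with no present genes are flagged absent.
#'
#' @param scaled_matrix output of [scale_genes()].
#' @param signatures named list of gene vectors.
#' @return list: `scores` (signatures x samples matrix, NA rows for absent
#'   signatures), `n_present` (genes found per signature).
#' @export
score_signatures <- function(scaled_matrix, signatures) {
  stopifnot(length(signatures) > 0, !is.null(names(signatures)))
  scores <- matrix(NA_real_, length(signatures), ncol(scaled_matrix),
                   dimnames = list(names(signatures), colnames(scaled_matrix)))
  n_present <- stats::setNames(integer(length(signatures)), names(signatures))
  for (nm in names(signatures)) {
    present <- intersect(signatures[[nm]], rownames(scaled_matrix))
    n_present[nm] <- length(present)
    if (length(present))
      scores[nm, ] <- colMeans(scaled_matrix[present, , drop = FALSE])
  }
  list(scores = scores, n_present = n_present)
}

#' Compare signature scores between young and older samples
#'
#' Two-sided Wilcoxon rank-sum test per signature between samples aged
#' <= `young_max` and >= `old_min` (intermediate ages excluded), with
#' Holm-Bonferroni adjustment across all tested signatures and direction
#' from group medians.
#'
#' @param scores signatures x samples matrix.
#' @param ages numeric sample ages.
#' @param young_max,old_min age-group cutoffs (defaults 35 and 50).
#' @return data.frame: `signature`, `median_young`, `median_old`,
#'   `direction` ("up"/"down" with age), `p_value`, `adjusted_p`.
#' @export
compare_age_groups <- function(scores, ages, young_max = 35, old_min = 50) {
  young <- ages <= young_max
  old <- ages >= old_min
  if (sum(young) < 2L || sum(old) < 2L) stop("age groups must have >= 2 samples")
  tested <- rownames(scores)[!apply(is.na(scores), 1L, all)]
  res <- lapply(tested, function(nm) {
    sy <- scores[nm, young]; so <- scores[nm, old]
    wt <- stats::wilcox.test(sy, so, exact = FALSE)
    data.frame(signature = nm,
               median_young = stats::median(sy), median_old = stats::median(so),
               direction = ifelse(stats::median(so) >= stats::median(sy),
                                  "up", "down"),
               p_value = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "holm")
  rownames(out) <- NULL
  out
}
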