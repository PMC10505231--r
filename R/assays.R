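## The two reference labeling rules the model is trained against and
## compared with: the NGS mean-arm-fold-change classification rule and the
## FISH signal-ratio deletion call.

#' Mean arm-level fold change from a gene-level log2 FC table
#'
#' Per-gene log2 fold changes are converted to the linear scale (2^log2fc)
#' and averaged arithmetically over the genes of the arm. The 0.8 decision
#' threshold and the expected 0.5-0.8 deleted range are linear-scale
#' quantities, so the linear mean is the default; `scale = "log2"` instead
#' averages in log2 space and exponentiates the result.
#'
#' @param gene_fc Data frame with columns `gene`, `arm` (`"1p"`/`"19q"`),
#'   `log2_fc`.
#' @param arm Which arm to average.
#' @param scale `"linear"` (default) or `"log2"`.
#' @return Mean fold change (linear scale) for the arm.
#' @export
mean_arm_fc <- function(gene_fc, arm = c("1p", "19q"), scale = c("linear", "log2")) {
  arm <- rlang::arg_match(arm)
  scale <- rlang::arg_match(scale)
  if (!all(c("arm", "log2_fc") %in% names(gene_fc))) {
    abort("`gene_fc` needs columns `arm` and `log2_fc`")
  }
  lfc <- gene_fc$log2_fc[gene_fc$arm == arm]
  if (length(lfc) < 1L) abort(sprintf("no genes on arm %s", arm))
  if (anyNA(lfc) || any(!is.finite(lfc))) abort("log2_fc values must be finite")
  switch(scale, linear = mean(2^lfc), log2 = 2^mean(lfc))
}

#' NGS tumor-type classification from mean arm fold changes
#'
#' Oligodendroglioma iff both arm means are strictly below `threshold`
#' (default 0.8); otherwise astrocytoma. A mean exactly at the threshold is
#' not-less-than, hence astrocytoma, and is flagged borderline (in practice
#' such genomes are re-reviewed on the copy-number plots).
#'
#' @param mean_1p,mean_19q Mean linear-scale fold change per arm.
#' @param threshold Decision threshold (default 0.8).
#' @return One-row tibble with `tumor_type` and `borderline`.
#' @export
ngs_classify <- function(mean_1p, mean_19q, threshold = 0.8) {
  stopifnot(is.finite(mean_1p), is.finite(mean_19q))
  type <- if (mean_1p < threshold && mean_19q < threshold) {
    "oligodendroglioma"
  } else {
    "astrocytoma"
  }
  borderline <- isTRUE(all.equal(mean_1p, threshold)) ||
    isTRUE(all.equal(mean_19q, threshold))
  tibble::tibble(tumor_type = type, borderline = borderline)
}

#' FISH deletion call from nucleus counts
#'
#' Nuclei are evaluable when they carry two centromeric (control) signals;
#' more than `min_nuclei` (strictly) must be evaluated. Deletion is called
#' iff the signal ratio `n_single_target / n_evaluated` strictly exceeds
#' `ratio_threshold` (default 50%).
#'
#' @param n_evaluated Count of evaluated nuclei (two control signals).
#' @param n_single_target Count of those nuclei with a single target-region
#'   signal.
#' @param min_nuclei Strict minimum of evaluated nuclei (default 60).
#' @param ratio_threshold Signal-ratio threshold (default 0.5).
#' @return One-row tibble with `call` (`"deleted"`/`"not_deleted"`) and
#'   `signal_ratio`.
#' @export
fish_deletion_call <- function(n_evaluated, n_single_target,
                               min_nuclei = 60L, ratio_threshold = 0.5) {
  assert_count(n_evaluated, "n_evaluated", min = 0L)
  assert_count(n_single_target, "n_single_target", min = 0L)
  if (n_single_target > n_evaluated) {
    abort("`n_single_target` cannot exceed `n_evaluated`")
  }
  if (n_evaluated <= min_nuclei) {
    abort(sprintf("insufficient nuclei: %d evaluated, more than %d required",
                  n_evaluated, min_nuclei))
  }
  ratio <- n_single_target / n_evaluated
  tibble::tibble(call = if (ratio > ratio_threshold) "deleted" else "not_deleted",
                 signal_ratio = ratio)
}

#' Joint 1p/19q codeletion status from two FISH calls
#'
#' @param call_1p,call_19q `"deleted"` or `"not_deleted"`.
#' @return `"codeleted"` iff both arms are deleted, else `"not_codeleted"`.
#' @export
fish_codeletion <- function(call_1p, call_19q) {
  ok <- c("deleted", "not_deleted")
  if (!call_1p %in% ok || !call_19q %in% ok) {
    abort("calls must be 'deleted' or 'not_deleted'")
  }
  if (call_1p == "deleted" && call_19q == "deleted") "codeleted" else "not_codeleted"
}
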