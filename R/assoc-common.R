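#' Association result container
#'
#' Uniform return value of all association tests: the association measure,
#' whether small values (p-values) or large values (log10 Bayes factors)
#' indicate stronger association, and method-specific per-trait detail.
#'
#' @param method Method identifier string.
#' @param measure Numeric association measure.
#' @param measure_kind `"p_value"` or `"log10_bf"`.
#' @param detail Optional list of method-specific detail (loadings,
#'   per-trait betas, partition posteriors, averaged weights, ...).
#' @return An object of class `"assoc_result"`.
#' @export
assoc_result <- function(method, measure, measure_kind = c("p_value", "log10_bf"),
                         detail = list()) {
  measure_kind <- match.arg(measure_kind)
  if (measure_kind == "p_value" && (measure <= 0 || measure > 1)) {
    stop("p-value measures must lie in (0, 1]", call. = FALSE)
  }
  structure(list(method = method, measure = measure,
                 measure_kind = measure_kind, detail = detail),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  lab <- if (x$measure_kind == "p_value") "p" else "log10 BF"
  cat(sprintf("%s: %s = %.4g\n", x$method, lab, x$measure))
  invisible(x)
}

stop_monomorphic <- function(what = "genotype") {
  stop(structure(
    class = c("mvqtlsim_monomorphic", "error", "condition"),
    list(message = paste0("monomorphic input: ", what,
                          " is constant in this sample"),
         call = sys.call(-1))
  ))
}

stop_convergence <- function(msg, diagnostics = NULL) {
  stop(structure(
    class = c("mvqtlsim_convergence", "error", "condition"),
    list(message = msg, call = sys.call(-1), diagnostics = diagnostics)
  ))
}

as_trait_matrix <- function(traits) {
  Y <- as.matrix(traits)
  storage.mode(Y) <- "double"
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  Y
}

check_genotype <- function(genotype, n = NULL) {
  g <- as.numeric(genotype)
  if (!is.null(n) && length(g) != n) {
    stop("genotype and trait dimensions disagree", call. = FALSE)
  }
  if (max(g) == min(g)) stop_monomorphic("genotype")
  g
}
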