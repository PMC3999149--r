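#' Write a dataset as a plain whitespace-delimited table
#'
#' Canonical on-disk dialect: one row per individual with columns
#' `ID`, `G` (minor-allele dosage) and `Y1..Yk`, space-delimited with a
#' header line. Values round-trip exactly through [read_dataset()] via
#' full-precision formatting.
#'
#' @param dataset A `sim_dataset` (or list with `genotype` and `traits`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  Y <- as_trait_matrix(dataset$traits)
  df <- data.frame(ID = seq_len(nrow(Y)), G = dataset$genotype)
  for (j in seq_len(ncol(Y))) df[[colnames(Y)[j]]] <- sprintf("%.17g", Y[, j])
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' Read a dataset from a plain table or SNPTEST-style pair
#'
#' The `"table"` dialect expects the [write_dataset()] layout (`ID G
#' Y1..Yk`). The `"gen"` dialect reads a SNPTEST-style `.gen`/`.sample`
#' pair, converting genotype probabilities to expected dosages; such
#' non-integer dosages are valid input for the Bayesian multivariate test
#' only, and `allow_dosage` must be set to accept them.
#'
#' @param path Path to the table (or `.gen` file for the `"gen"` dialect).
#' @param dialect `"table"` or `"gen"`.
#' @param sample_path `.sample` file for the `"gen"` dialect.
#' @param allow_dosage Accept non-integer genotype values.
#' @return A list with `genotype` and `traits`, shaped like a
#'   `sim_dataset`.
#' @export
read_dataset <- function(path, dialect = c("table", "gen"),
                         sample_path = NULL, allow_dosage = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "table") {
    lines <- readLines(path)
    if (length(lines) < 2L) {
      stop("parse error in ", path, ": no data rows", call. = FALSE)
    }
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(header) < 3L || header[1] != "ID" || header[2] != "G") {
      stop("parse error in ", path, " line 1: expected header 'ID G Y1...'",
           call. = FALSE)
    }
    ncol_exp <- length(header)
    rows <- strsplit(trimws(lines[-1]), "\\s+")
    bad <- which(lengths(rows) != ncol_exp)
    if (length(bad)) {
      stop("parse error in ", path, " line ", bad[1] + 1L,
           ": expected ", ncol_exp, " fields, found ",
           lengths(rows)[bad[1]], call. = FALSE)
    }
    m <- suppressWarnings(
      matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE))
    if (anyNA(m)) {
      bad <- which(apply(m, 1, anyNA))[1]
      stop("parse error in ", path, " line ", bad + 1L,
           ": non-numeric field", call. = FALSE)
    }
    g <- m[, 2]
    Y <- m[, -(1:2), drop = FALSE]
    colnames(Y) <- header[-(1:2)]
  } else {
    if (is.null(sample_path)) {
      stop("the 'gen' dialect needs `sample_path`", call. = FALSE)
    }
    gen <- utils::read.table(path, header = FALSE)
    probs <- as.numeric(gen[1, -(1:5)])
    if (length(probs) %% 3 != 0) {
      stop("parse error in ", path, ": genotype probabilities not in ",
           "triples", call. = FALSE)
    }
    pm <- matrix(probs, ncol = 3, byrow = TRUE)
    g <- pm[, 2] + 2 * pm[, 3]  # expected minor-allele dosage
    smp <- utils::read.table(sample_path, header = TRUE,
                             stringsAsFactors = FALSE)
    smp <- smp[-1, , drop = FALSE]  # drop the type line
    ycols <- setdiff(names(smp), c("ID_1", "ID_2", "missing"))
    Y <- as.matrix(vapply(smp[ycols], as.numeric, numeric(nrow(smp))))
    colnames(Y) <- ycols
  }
  if (!allow_dosage && !all(g %in% c(0, 1, 2))) {
    stop("genotype values outside {0,1,2}; set `allow_dosage = TRUE` to ",
         "accept expected dosages (Bayesian multivariate test only)",
         call. = FALSE)
  }
  list(genotype = g, traits = Y)
}

#' Write PLINK-style .ped/.map files (write-only interoperability)
#'
#' Field order: `.ped` holds family ID, individual ID, paternal and
#' maternal IDs (0), sex (0), the first trait as the phenotype column, and
#' two allele columns coding the QTL genotype with alleles `A` (major) and
#' `B` (minor); `.map` holds chromosome 1, marker `qtl`, genetic distance
#' 0, position 1.
#'
#' @param dataset A `sim_dataset`-shaped list.
#' @param prefix Output path prefix (writes `prefix.ped`, `prefix.map` and
#'   `prefix.phen` with all traits).
#' @return `prefix`, invisibly.
#' @export
write_plink_ped <- function(dataset, prefix) {
  g <- dataset$genotype
  Y <- as_trait_matrix(dataset$traits)
  n <- length(g)
  a1 <- ifelse(g >= 1, "B", "A")
  a2 <- ifelse(g == 2, "B", "A")
  ped <- data.frame(FID = seq_len(n), IID = seq_len(n), PAT = 0, MAT = 0,
                    SEX = 0, PHEN = sprintf("%.17g", Y[, 1]),
                    A1 = a1, A2 = a2)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  writeLines("1 qtl 0 1", paste0(prefix, ".map"))
  phen <- data.frame(FID = seq_len(n), IID = seq_len(n))
  for (j in seq_len(ncol(Y))) {
    phen[[colnames(Y)[j]]] <- sprintf("%.17g", Y[, j])
  }
  utils::write.table(phen, paste0(prefix, ".phen"), quote = FALSE,
                     row.names = FALSE, sep = " ")
  invisible(prefix)
}

#' Write SNPTEST-style .gen/.sample files (write-only interoperability)
#'
#' The `.gen` row is `1 qtl 1 A B` followed by hard-call genotype
#' probability triples; the `.sample` file carries the trait columns typed
#' `P` (quantitative phenotype).
#'
#' @param dataset A `sim_dataset`-shaped list.
#' @param prefix Output path prefix (writes `prefix.gen`, `prefix.sample`).
#' @return `prefix`, invisibly.
#' @export
write_snptest_gen <- function(dataset, prefix) {
  g <- dataset$genotype
  Y <- as_trait_matrix(dataset$traits)
  trip <- vapply(g, function(x) {
    c(as.integer(x == 0), as.integer(x == 1), as.integer(x == 2))
  }, integer(3))
  writeLines(paste(c("1", "qtl", "1", "A", "B", as.vector(trip)),
                   collapse = " "),
             paste0(prefix, ".gen"))
  n <- length(g)
  smp <- data.frame(ID_1 = seq_len(n), ID_2 = seq_len(n), missing = 0)
  for (j in seq_len(ncol(Y))) {
    smp[[colnames(Y)[j]]] <- sprintf("%.17g", Y[, j])
  }
  con <- file(paste0(prefix, ".sample"), "w")
  writeLines(paste(names(smp), collapse = " "), con)
  writeLines(paste(c("0", "0", "0", rep("P", ncol(Y))), collapse = " "), con)
  utils::write.table(smp, con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  close(con)
  invisible(prefix)
}

#' Read a study configuration file
#'
#' YAML (or JSON-compatible YAML) configuration with keys
#' `n_individuals`, `maf`, `h2`, `effect_sign`, `residual_corr`,
#' `n_replicates`, `n_permutations`, `seed` (mandatory: no wall-clock
#' seeding), and optionally `methods`, `alpha` and per-method settings
#' (`priors`, `pch`). A config may instead set `grid: default` (plus
#' optional overrides) to request the full scenario grid.
#'
#' @param path Path to the configuration file.
#' @return A list with `scenarios` (list of [scenario_spec()]),
#'   `methods`, `alpha`, `priors`, `pch`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) {
    stop("config must set `seed` explicitly", call. = FALSE)
  }
  methods <- if (is.null(cfg$methods)) c("uv", "cca", "bayes")
             else as.character(cfg$methods)
  unknown <- setdiff(methods, mv_methods())
  if (length(unknown)) {
    stop("unknown method id(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  take <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  if (identical(cfg$grid, "default")) {
    scenarios <- scenario_grid(
      n_individuals = take("n_individuals", 1000L),
      n_replicates = take("n_replicates", 1000L),
      n_permutations = take("n_permutations", 10L),
      seed = cfg$seed)
  } else {
    scenarios <- list(scenario_spec(
      n_individuals = take("n_individuals", 1000L),
      maf = take("maf", 0.4),
      h2 = take("h2", c(0.001, 0, 0)),
      effect_sign = cfg$effect_sign,
      residual_corr = take("residual_corr", 0),
      n_replicates = take("n_replicates", 1000L),
      n_permutations = take("n_permutations", 10L),
      seed = cfg$seed))
  }
  priors <- if (is.null(cfg$priors)) bayes_priors()
            else do.call(bayes_priors, cfg$priors)
  pch <- if (is.null(cfg$pch)) pch_settings()
         else do.call(pch_settings, cfg$pch)
  list(scenarios = scenarios, methods = methods,
       alpha = take("alpha", 0.05), priors = priors, pch = pch)
}

#' Write the study tables as TSV
#'
#' @param study An `"mv_study"` from [run_study()].
#' @param dir Output directory (created if needed); writes
#'   `thresholds.tsv` and `power.tsv`.
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(study, dir) {
  stopifnot(inherits(study, "mv_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$thresholds, file.path(dir, "thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$power, file.path(dir, "power.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Summarize a results directory
#'
#' Reads `thresholds.tsv` and `power.tsv` from a results directory and
#' assembles scenario-family summaries: thresholds grouped by measure kind
#' (p-value methods vs Bayes-factor methods) with their achieved
#' type-I-error rate, and a scenario x method power matrix.
#'
#' @param dir Results directory produced by [write_study_tables()].
#' @return A list of class `"mv_report"` with `thresholds`,
#'   `power_matrix` (scenarios x methods, in percent) and `power` (long
#'   form).
#' @export
report <- function(dir) {
  need <- file.path(dir, c("thresholds.tsv", "power.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  thr <- utils::read.delim(need[1], stringsAsFactors = FALSE)
  pow <- utils::read.delim(need[2], stringsAsFactors = FALSE)
  thr <- thr[order(thr$measure_kind, thr$method, thr$scenario), ]
  pm <- stats::xtabs(power ~ scenario + method, data = pow)
  structure(list(thresholds = thr, power = pow,
                 power_matrix = as.matrix(pm)),
            class = "mv_report")
}

#' @export
print.mv_report <- function(x, ...) {
  cat("Empirical significance thresholds (achieved type-I error = target):\n")
  for (kind in unique(x$thresholds$measure_kind)) {
    cat(" ", kind, "methods:\n")
    sub <- x$thresholds[x$thresholds$measure_kind == kind, ]
    print(sub[, c("scenario", "method", "threshold", "achieved_rate")],
          row.names = FALSE)
  }
  cat("\nPower (%):\n")
  print(round(x$power_matrix, 1))
  invisible(x)
}

#' Grouped bar chart of a power table
#'
#' Base-graphics grouped bars, one group per scenario, one bar per method.
#'
#' @param study An `"mv_study"` or `"mv_report"`.
#' @param main Plot title.
#' @return Invisibly, the matrix plotted.
#' @export
plot_power <- function(study, main = "Power at the empirical 5% threshold") {
  pow <- study$power
  pm <- t(stats::xtabs(power ~ scenario + method, data = pow))
  graphics::barplot(pm, beside = TRUE, legend.text = rownames(pm),
                    ylab = "power (%)", las = 2, main = main,
                    args.legend = list(x = "topleft", bty = "n", cex = 0.8))
  invisible(pm)
}
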