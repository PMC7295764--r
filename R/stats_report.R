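# Two-group statistics and report tables shared by all stages.

#' Mean and standard error of the mean
#'
#' @param values numeric vector (n >= 1).
#' @return list with `mean`, `sem` (`NA` at n = 1, where the SEM is
#'   undefined), `n`.
#' @export
summarize_mean_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty input")
  list(mean = mean(values),
       sem = if (length(values) > 1L) stats::sd(values) / sqrt(length(values))
             else NA_real_,
       n = length(values))
}

#' Two-sample Student's t-test
#'
#' Equal-variance, two-sided Student's form (Welch's correction available via
#' `welch = TRUE`). Degenerate input with zero variance in both groups and
#' equal means is reported as t = 0, p = 1 by convention.
#'
#' @param sample_a,sample_b numeric vectors (n >= 2 each).
#' @param alpha significance level for the `significant` flag.
#' @param welch use Welch's unequal-variance form.
#' @param labels group labels for reporting.
#' @return object of class `group_comparison`: list with per-group n, mean,
#'   sem, plus `t_statistic`, `df`, `p_value`, `significant`, `alpha`.
#' @export
two_group_ttest <- function(sample_a, sample_b, alpha = 0.05, welch = FALSE,
                            labels = c("a", "b")) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("need n >= 2 per group")
  sa <- summarize_mean_sem(sample_a); sb <- summarize_mean_sem(sample_b)
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    equal <- isTRUE(all.equal(sa$mean, sb$mean))
    t <- if (equal) 0 else sign(sa$mean - sb$mean) * Inf
    p <- if (equal) 1 else 0
    df <- length(sample_a) + length(sample_b) - 2L
  } else {
    tt <- stats::t.test(sample_a, sample_b, var.equal = !welch)
    t <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
  }
  structure(list(labels = labels, n = c(sa$n, sb$n), mean = c(sa$mean, sb$mean),
                 sem = c(sa$sem, sb$sem), t_statistic = t, df = df,
                 p_value = p, significant = p < alpha, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("<group_comparison> %s: %.4g +/- %.2g (n = %d) vs ",
                     "%s: %.4g +/- %.2g (n = %d)\n",
                     "  t = %.4g, df = %.4g, p = %.3g%s\n"),
              x$labels[1L], x$mean[1L], x$sem[1L], x$n[1L],
              x$labels[2L], x$mean[2L], x$sem[2L], x$n[2L],
              x$t_statistic, x$df, x$p_value,
              if (x$significant) sprintf(" (significant at alpha = %g)", x$alpha)
              else ""))
  invisible(x)
}

#' Write a delimited summary table for a group comparison
#'
#' @param comparison a [two_group_ttest()] result.
#' @param path output path (comma-separated text).
#' @export
write_group_comparison <- function(comparison, path) {
  df <- data.frame(group = comparison$labels, n = comparison$n,
                   mean = comparison$mean, sem = comparison$sem,
                   t_statistic = comparison$t_statistic,
                   p_value = comparison$p_value)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records the configuration (hashed), seeds and package/R versions of an
#' analysis run as YAML.
#'
#' @param path output path.
#' @param config list of run parameters (hashed with md5 and stored).
#' @param seeds named list/vector of seeds used.
#' @export
write_run_manifest <- function(path, config = list(), seeds = list()) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  man <- list(written = format(Sys.time(), tz = "UTC", usetz = TRUE),
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("spheroquant")),
              config = config,
              config_md5 = unname(tools::md5sum(tmp)),
              seeds = seeds)
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Read and validate a structured-text run configuration
#'
#' YAML with a required `stage` field; remaining fields are stage parameters.
#' Unknown fields are kept; missing required fields raise an error.
#'
#' @param path YAML file.
#' @param required character vector of required field names.
#' @return named list.
#' @export
read_run_config <- function(path, required = "stage") {
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config missing required field(s): ", paste(missing, collapse = ", "))
  cfg
}
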