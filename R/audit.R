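#' Audit whether impairment ratings are interchangeable with botheredness
#'
#' The package's main entry point. Runs the full analysis plan on a table
#' of paired impairment/botheredness ratings: validation, descriptive
#' summaries, tie-aware Spearman correlation with a permutation
#' significance test per item and for the pooled pairs, and the paired
#' sign-flip randomization test of interchangeability per item and for
#' the pooled differences. All resampling is driven by one master seed;
#' each test receives a distinct sub-seed derived deterministically from
#' the seed, the row label and the test name, so results are reproducible
#' and adding an item never perturbs another item's test.
#'
#' @param data a [ratings_table()] object, a data frame with columns
#'   `respondent_id`, `item`, `impaired`, `bothered`, a [sim_config()]
#'   (the table is generated), or a path to a long-dialect CSV file.
#' @param n_resamples Monte Carlo resamples per test (default 10,000).
#' @param seed master seed.
#' @param tail tail rule for the correlation permutation test (see
#'   [permutation_test_rho()]).
#' @param p_convention Monte Carlo p-value convention (`"add_one"` or
#'   `"plug_in"`).
#' @param alpha significance level for decision columns.
#' @param combined_mode `"pooled"` (concatenate item-level pairs) or
#'   `"sums"` (per-respondent scale totals).
#' @param strict abort on any validation violation (lenient mode drops
#'   invalid records at read time instead).
#' @param exact_threshold enumerate all permutations of the correlation
#'   test when n is at or below this (default 7).
#' @param signflip_exact_threshold enumerate all 2^n sign assignments
#'   when n is at or below this (default 20).
#' @return A `wsas_audit` object with components `validation`,
#'   `descriptives` (per item and rating kind), `medians`, `association`
#'   and `interchangeability` (each one `resample_result` per row label,
#'   Combined first), `config`, `version`, `timestamp`.
#' @export
#' @examples
#' tab <- generate_ratings(sim_config(30,
#'   lapply(names(wsas_items()), item_spec, latent_correlation = 0.6),
#'   seed = 2))
#' wsas_audit(tab, n_resamples = 1000, seed = 9)
wsas_audit <- function(data, n_resamples = 10000, seed = 1,
                       tail = c("one_sided_greater", "two_sided_absolute"),
                       p_convention = c("add_one", "plug_in"),
                       alpha = 0.05,
                       combined_mode = c("pooled", "sums"),
                       strict = TRUE, exact_threshold = 7,
                       signflip_exact_threshold = 20) {
  tail <- match.arg(tail)
  p_convention <- match.arg(p_convention)
  combined_mode <- match.arg(combined_mode)

  table <- resolve_input(data, strict)
  validation <- validate_ratings(table)
  if (strict && !validation$strict_pass)
    stopf("strict validation failed: %d out of range, %d duplicates, %d missing",
          validation$n_out_of_range, validation$n_duplicates,
          validation$n_missing)

  df <- as.data.frame(table)
  items <- names(wsas_items())[names(wsas_items()) %in% unique(df$item)]

  descriptives <- list()
  for (it in items) for (kind in c("impaired", "bothered"))
    descriptives[[paste(it, kind, sep = ".")]] <-
      summarize_ratings(table, it, kind)
  medians <- compare_medians(table)

  association <- list()
  for (lab in audit_labels(items)) {
    pv <- if (lab == "combined") {
      if (combined_mode == "sums") summed_pairs(table) else pooled_pairs(table)
    } else item_pairs(table, lab)
    association[[lab]] <- tryCatch(
      permutation_test_rho(pv$x, pv$y, n_resamples = n_resamples,
                           seed = derive_seed(seed, lab, "rho"),
                           tail = tail, p_convention = p_convention,
                           exact_threshold = exact_threshold, label = lab),
      error = function(e) structure(list(label = lab,
                                         error = conditionMessage(e)),
                                    class = "resample_error"))
  }

  interchangeability <- interchangeability_table(
    table, n_resamples = n_resamples, seed = seed, alpha = alpha,
    p_convention = p_convention,
    exact_threshold = signflip_exact_threshold,
    combined_mode = combined_mode)

  structure(list(
    validation = validation,
    descriptives = descriptives,
    medians = medians,
    association = association,
    interchangeability = interchangeability,
    config = list(n_resamples = n_resamples, seed = seed, tail = tail,
                  p_convention = p_convention, alpha = alpha,
                  combined_mode = combined_mode, strict = strict,
                  exact_threshold = exact_threshold,
                  signflip_exact_threshold = signflip_exact_threshold,
                  provenance = attr(table, "provenance") %||% "unknown",
                  n_respondents = length(unique(df$respondent_id)),
                  items = items),
    version = as.character(utils::packageVersion("bothaudit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "wsas_audit")
}

resolve_input <- function(data, strict) {
  if (inherits(data, "wsas_ratings")) return(data)
  if (inherits(data, "sim_config")) return(generate_ratings(data))
  if (is.character(data) && length(data) == 1)
    return(read_ratings(data, dialect = "long", strict = strict))
  if (is.data.frame(data))
    return(ratings_table(data$respondent_id, data$item, data$impaired,
                         data$bothered, strict = strict,
                         provenance = "data.frame"))
  stopf("cannot interpret 'data': supply a ratings table, data frame, sim_config or CSV path")
}

audit_rows <- function(results, alpha = NULL) {
  do.call(rbind, lapply(names(results), function(lab) {
    r <- results[[lab]]
    if (inherits(r, "resample_error"))
      return(data.frame(label = display_label(lab), observed = NA_real_,
                        p_value = NA_real_, n_resamples = NA_integer_,
                        exact = NA, error = r$error,
                        stringsAsFactors = FALSE))
    data.frame(label = display_label(lab), observed = r$observed,
               p_value = r$p_value, n_resamples = r$n_resamples,
               exact = r$exact, error = "", stringsAsFactors = FALSE)
  }))
}

#' @export
print.wsas_audit <- function(x, ...) {
  cat("Interchangeability audit of paired impairment/botheredness ratings\n")
  cat(sprintf("  %d respondents, %d records (%s)\n",
              x$config$n_respondents, x$validation$n_records,
              x$config$provenance))
  cat(sprintf("  resamples = %s, seed = %d, alpha = %.2f\n\n",
              format(x$config$n_resamples, big.mark = ","),
              x$config$seed, x$config$alpha))
  a <- audit_rows(x$association)
  cat("Spearman correlation (impaired vs bothered), permutation test:\n")
  print_block(a)
  i <- audit_rows(x$interchangeability)
  i$reject <- ifelse(i$p_value <= x$config$alpha, "reject", "retain")
  cat("\nMean difference (impaired - bothered), sign-flip test:\n")
  print_block(i, decision = TRUE)
  invisible(x)
}

print_block <- function(rows, decision = FALSE) {
  for (k in seq_len(nrow(rows))) {
    r <- rows[k, ]
    if (nzchar(r$error)) {
      cat(sprintf("  %-16s <error: %s>\n", r$label, r$error)); next
    }
    cat(sprintf("  %-16s %8.4f   p = %.4f%s%s\n", r$label, r$observed,
                r$p_value, if (r$exact) " (exact)" else "",
                if (decision) paste0("   ", r$reject) else ""))
  }
}

#' @export
summary.wsas_audit <- function(object, ...) {
  print(object)
  cat("\nPer-item medians (impaired vs bothered):\n")
  m <- object$medians
  for (k in seq_len(nrow(m)))
    cat(sprintf("  %-16s %.1f vs %.1f  %s\n", display_label(m$item[k]),
                m$impaired_median[k], m$bothered_median[k],
                if (m$differs[k]) paste0("higher: ", m$higher[k]) else "tie"))
  invisible(object)
}

#' @export
plot.wsas_audit <- function(x, ...) {
  d <- x$descriptives
  items <- x$config$items
  old <- graphics::par(mfrow = c(1, length(items)), mar = c(6, 3, 2, 1))
  on.exit(graphics::par(old))
  for (it in items) {
    imp <- d[[paste(it, "impaired", sep = ".")]]$counts_by_level
    bot <- d[[paste(it, "bothered", sep = ".")]]$counts_by_level
    graphics::barplot(rbind(imp, bot), beside = TRUE,
                      col = c("#0072B2", "#E69F00"),
                      main = display_label(it), las = 1, ...)
  }
  invisible(x)
}

#' Write an audit report to disk
#'
#' JSON is the canonical nested format and round-trips through
#' [read_report()]; CSV is a flat table of all test rows; markdown
#' renders the two report tables (one row per item plus a Combined row).
#' Coefficients and p-values are serialized at 4 decimal places.
#'
#' @param report a `wsas_audit` object.
#' @param path output file path.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (format == "csv") {
    a <- audit_rows(report$association)
    i <- audit_rows(report$interchangeability)
    flat <- rbind(cbind(section = "association", a),
                  cbind(section = "interchangeability", i))
    flat$observed <- sprintf("%.4f", flat$observed)
    flat$p_value <- sprintf("%.4f", flat$p_value)
    utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- c("# Interchangeability audit", "",
               "## Spearman correlation (impaired vs bothered)", "",
               "| WSAS ratings | Correlation coefficient | p |",
               "|---|---|---|",
               md_rows(report$association),
               "", "## Mean difference (impaired - bothered)", "",
               "| WSAS ratings | Mean difference | p |",
               "|---|---|---|",
               md_rows(report$interchangeability))
    writeLines(lines, path)
  }
  invisible(path)
}

md_rows <- function(results) {
  vapply(names(results), function(lab) {
    r <- results[[lab]]
    if (inherits(r, "resample_error"))
      return(sprintf("| %s | error | %s |", display_label(lab), r$error))
    sprintf("| %s | %.4f | %.4f |", display_label(lab), r$observed, r$p_value)
  }, character(1))
}

report_as_list <- function(report) {
  num <- function(v) round(v, 4)
  res_list <- function(results) lapply(results, function(r) {
    if (inherits(r, "resample_error"))
      return(list(label = r$label, error = r$error))
    list(label = r$label, observed = num(r$observed),
         p_value = num(r$p_value), n_resamples = r$n_resamples,
         n_as_extreme = r$n_as_extreme, tail = r$tail,
         p_convention = r$p_convention, exact = r$exact,
         seed = if (is.na(r$seed)) NULL else r$seed)
  })
  list(validation = unclass(report$validation),
       descriptives = lapply(report$descriptives, function(s) {
         s <- unclass(s)
         s$counts_by_level <- as.integer(s$counts_by_level)
         s[c("item", "rating_kind", "n", "mean", "median", "q1", "q3",
             "iqr", "min", "max", "skewness", "counts_by_level")]
       }),
       medians = report$medians,
       association = res_list(report$association),
       interchangeability = res_list(report$interchangeability),
       config = report$config,
       version = report$version,
       timestamp = report$timestamp)
}

#' Read back a JSON audit report
#'
#' @param path path to a JSON file written by [write_report()].
#' @return The parsed report as a nested list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
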