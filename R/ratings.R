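#' Construct a paired ratings table
#'
#' A `wsas_ratings` object holds one record per respondent and item with a
#' paired impairment rating and botheredness rating, each an integer from
#' 0 (not at all) to 8 (very severely / very, very bothered).
#'
#' @param respondent_id character vector of opaque respondent identifiers.
#' @param item character vector of item tokens (see [wsas_items()]).
#' @param impaired,bothered integer ratings in 0--8 (NA allowed only when
#'   `strict = FALSE`).
#' @param strict logical; if `TRUE` (default) any invalid record is an
#'   error, if `FALSE` invalid records are dropped with a message.
#' @param provenance free text recording where the data came from.
#' @return A `wsas_ratings` data frame with columns `respondent_id`,
#'   `item`, `impaired`, `bothered` and attribute `provenance`.
#' @export
#' @examples
#' ratings_table("p1", "home", 6, 8)
ratings_table <- function(respondent_id, item, impaired, bothered,
                          strict = TRUE, provenance = "in-memory") {
  df <- data.frame(respondent_id = as.character(respondent_id),
                   item          = as.character(item),
                   impaired      = suppressWarnings(as.integer(impaired)),
                   bothered      = suppressWarnings(as.integer(bothered)),
                   stringsAsFactors = FALSE)
  bad_item  <- !(df$item %in% names(wsas_items()))
  missing   <- is.na(df$impaired) | is.na(df$bothered)
  in_range  <- function(v) !is.na(v) & v >= 0L & v <= 8L
  out_range <- (!is.na(df$impaired) & !in_range(df$impaired)) |
               (!is.na(df$bothered) & !in_range(df$bothered))
  dup       <- duplicated(df[, c("respondent_id", "item")]) |
               duplicated(df[, c("respondent_id", "item")], fromLast = TRUE)
  dup_first <- duplicated(df[, c("respondent_id", "item")])

  if (strict) {
    if (any(bad_item))
      stopf("row %d: unknown item '%s' (expected one of: %s)",
            which(bad_item)[1], df$item[which(bad_item)[1]],
            paste(names(wsas_items()), collapse = ", "))
    if (any(out_range))
      stopf("row %d: rating outside the 0-8 scale (impaired=%s, bothered=%s)",
            which(out_range)[1], df$impaired[which(out_range)[1]],
            df$bothered[which(out_range)[1]])
    if (any(missing))
      stopf("row %d: missing rating for respondent '%s', item '%s'",
            which(missing)[1], df$respondent_id[which(missing)[1]],
            df$item[which(missing)[1]])
    if (any(dup))
      stopf("duplicate (respondent, item) pair: ('%s', '%s')",
            df$respondent_id[which(dup)[1]], df$item[which(dup)[1]])
  } else {
    drop <- bad_item | out_range | missing | dup_first
    if (any(drop)) {
      message(sprintf(
        "dropping %d invalid record(s): %d bad item, %d out of range, %d missing, %d duplicate",
        sum(drop), sum(bad_item), sum(out_range & !bad_item),
        sum(missing & !bad_item & !out_range), sum(dup_first)))
      df <- df[!drop, , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  structure(df, provenance = provenance,
            class = c("wsas_ratings", "data.frame"))
}

#' Read a paired ratings table from CSV
#'
#' Two dialects are supported. `long` has columns
#' `respondent_id,item,impaired,bothered` with one row per respondent-item.
#' `wide` has `respondent_id` followed by `impaired_<item>` and
#' `bothered_<item>` for each of the five items. Files are UTF-8,
#' comma-separated, with a mandatory header row; item labels are the
#' tokens of [wsas_items()]; ratings are bare integers.
#'
#' @param path path to a CSV file.
#' @param dialect `"long"` or `"wide"`.
#' @param strict logical; strict mode raises on any invalid record,
#'   lenient mode drops invalid records and reports counts.
#' @return A [ratings_table()] object.
#' @export
read_ratings <- function(path, dialect = c("long", "wide"), strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (dialect == "long") {
    need <- c("respondent_id", "item", "impaired", "bothered")
    if (!identical(names(df), need))
      stopf("long dialect requires header exactly '%s'; got '%s'",
            paste(need, collapse = ","), paste(names(df), collapse = ","))
    tab <- ratings_table(df$respondent_id, df$item, df$impaired,
                         df$bothered, strict = strict, provenance = path)
  } else {
    items <- names(wsas_items())
    need <- c("respondent_id",
              as.vector(rbind(paste0("impaired_", items),
                              paste0("bothered_", items))))
    if (!identical(sort(names(df)), sort(need)))
      stopf("wide dialect requires columns '%s'", paste(need, collapse = ","))
    long <- do.call(rbind, lapply(items, function(it) {
      data.frame(respondent_id = df$respondent_id, item = it,
                 impaired = df[[paste0("impaired_", it)]],
                 bothered = df[[paste0("bothered_", it)]],
                 stringsAsFactors = FALSE)
    }))
    # drop item rows a respondent left entirely blank (wide files carry a
    # cell for every item); in strict mode a blank is a missing rating
    if (!strict) {
      blank <- long$impaired == "" & long$bothered == ""
      long <- long[!blank, , drop = FALSE]
    }
    tab <- ratings_table(long$respondent_id, long$item, long$impaired,
                         long$bothered, strict = strict, provenance = path)
  }
  tab
}

#' Write a ratings table to CSV
#'
#' @param table a [ratings_table()] object.
#' @param path output file path.
#' @param dialect `"long"` or `"wide"` (see [read_ratings()]).
#' @return `path`, invisibly.
#' @export
write_ratings <- function(table, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(table)
  if (dialect == "long") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    ids <- unique(df$respondent_id)
    out <- data.frame(respondent_id = ids, stringsAsFactors = FALSE)
    for (it in names(wsas_items())) {
      sub <- df[df$item == it, , drop = FALSE]
      out[[paste0("impaired_", it)]] <- sub$impaired[match(ids, sub$respondent_id)]
      out[[paste0("bothered_", it)]] <- sub$bothered[match(ids, sub$respondent_id)]
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Validate a ratings table
#'
#' Counts violations of the rating-scale contract (integer 0--8, no
#' missing values, unique respondent-item pairs) without mutating the
#' table. `strict_pass` is `TRUE` iff every count is zero.
#'
#' @param table a [ratings_table()] object or a data frame with the long
#'   columns.
#' @return A `wsas_validation` list: `n_records`, `n_out_of_range`,
#'   `n_duplicates`, `n_missing`, `strict_pass`.
#' @export
validate_ratings <- function(table) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) {
    warning("validating an empty ratings table")
    rep <- list(n_records = 0L, n_out_of_range = 0L, n_duplicates = 0L,
                n_missing = 0L, strict_pass = TRUE)
    return(structure(rep, class = "wsas_validation"))
  }
  imp <- suppressWarnings(as.integer(df$impaired))
  bot <- suppressWarnings(as.integer(df$bothered))
  missing <- is.na(imp) | is.na(bot)
  oor <- (!is.na(imp) & (imp < 0L | imp > 8L)) |
         (!is.na(bot) & (bot < 0L | bot > 8L))
  dup <- duplicated(df[, c("respondent_id", "item")])
  rep <- list(n_records      = nrow(df),
              n_out_of_range = sum(oor),
              n_duplicates   = sum(dup),
              n_missing      = sum(missing & !oor),
              strict_pass    = !any(oor) && !any(dup) && !any(missing))
  structure(rep, class = "wsas_validation")
}

#' @export
print.wsas_validation <- function(x, ...) {
  cat(sprintf("Ratings validation: %d records; %d out of range, %d duplicates, %d missing -> %s\n",
              x$n_records, x$n_out_of_range, x$n_duplicates, x$n_missing,
              if (x$strict_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
print.wsas_ratings <- function(x, ...) {
  cat(sprintf("Paired WSAS ratings: %d records, %d respondents, %d item(s)\n",
              nrow(x), length(unique(x$respondent_id)),
              length(unique(x$item))))
  cat(sprintf("provenance: %s\n", attr(x, "provenance") %||% "unknown"))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}
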