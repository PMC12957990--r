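#' The five WSAS item areas
#'
#' The modified Work and Social Adjustment Scale rates impairment and
#' botheredness in five broad areas of functioning. Each area is identified
#' by a stable token (used in data files and config objects) and carries a
#' display name used in printed tables.
#'
#' @return Named character vector: names are the item tokens
#'   (`home`, `private_leisure`, `relationships`, `social_leisure`, `work`),
#'   values are display names.
#' @export
#' @examples
#' wsas_items()
wsas_items <- function() {
  c(home            = "Home",
    private_leisure = "Private Leisure",
    relationships   = "Relationships",
    social_leisure  = "Social Leisure",
    work            = "Work")
}

# Row order used in all per-item + pooled report tables: pooled first.
audit_labels <- function(items = names(wsas_items())) {
  c("combined", items[items %in% names(wsas_items())])
}

display_label <- function(label) {
  if (label == "combined") "Combined" else unname(wsas_items()[label])
}

#' Default category probabilities for ratings 0 to 8
#'
#' A right-skewed nine-category marginal with most mass on ratings 2--6,
#' chosen to emulate the non-normal rating distributions typical of
#' impairment questionnaires. This is a modelling choice: real per-item
#' marginals are not published, only that they departed from normality.
#'
#' @return Numeric vector of 9 probabilities (ratings 0--8) summing to 1.
#' @export
default_marginal_weights <- function() {
  c(0.04, 0.07, 0.12, 0.15, 0.17, 0.16, 0.13, 0.09, 0.07)
}

# Deterministic sub-seed derivation: fold a master seed and text labels
# through a polynomial hash mod (2^31 - 1). Adding an item or test never
# perturbs the stream of another, and results stay below 2^31.
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (lab in unlist(list(...))) {
    for (code in utf8ToInt(as.character(lab))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
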