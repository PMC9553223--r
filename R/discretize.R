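#' Quantile-bin continuous columns so Hamming distance is well defined
#'
#' Replaces every numeric and date column of a table by quantile-bin labels;
#' categorical and ordinal columns pass through unchanged. Cut-points are by
#' default learned from the table itself and returned with it, so a second
#' table can be binned with the *same* cut-points (pass them via `cutpoints`):
#' attack and synthetic tables must share the reference table's bins or
#' equality of bin labels is meaningless.
#'
#' When applying stored cut-points, values outside the reference range fall
#' into the first or last bin. Missing values stay missing and form their own
#' category during matching (equal only to another missing value). A constant
#' column collapses into a single bin.
#'
#' @param table A non-empty `record_table`.
#' @param cutpoints Optional named list of numeric break vectors from a
#'   previous `discretize()` call on the reference table.
#' @return A `record_table` whose continuous columns are categorical bin
#'   labels; the cut-points used are attached as `$cutpoints`.
#' @export
discretize <- function(table, cutpoints = NULL) {
  stopifnot(inherits(table, "record_table"))
  if (nrow(table$data) == 0L) stop("cannot discretize an empty table", call. = FALSE)
  kinds <- schema_kinds(table$schema)
  cont <- which(kinds %in% c("numeric", "date"))
  if (!length(cont)) {
    if (is.null(table$cutpoints)) table$cutpoints <- list()
    return(table)
  }
  used <- list()
  for (j in cont) {
    col <- table$schema[[j]]
    x <- table$data[[j]]
    xn <- if (inherits(x, "Date")) as.numeric(x) else x
    if (!is.null(cutpoints) && !is.null(cutpoints[[col$name]])) {
      breaks <- cutpoints[[col$name]]
    } else {
      obs <- xn[!is.na(xn)]
      if (!length(obs)) {
        breaks <- c(0, 0) # all-missing column: one (empty) bin
      } else {
        probs <- seq(0, 1, length.out = col$bins + 1L)
        breaks <- unique(unname(stats::quantile(obs, probs = probs, type = 7)))
        if (length(breaks) == 1L) breaks <- c(breaks, breaks)
      }
    }
    used[[col$name]] <- breaks
    # extend the outer breaks so out-of-range values land in the end bins
    apply_breaks <- breaks
    apply_breaks[1L] <- -Inf
    apply_breaks[length(apply_breaks)] <- Inf
    idx <- cut(xn, breaks = apply_breaks, labels = FALSE, include.lowest = TRUE)
    nb <- length(breaks) - 1L
    labels <- sprintf("bin%02d", seq_len(nb))
    out <- ifelse(is.na(idx), NA_character_, labels[idx])
    table$data[[j]] <- out
    table$schema[[j]]$kind <- "categorical"
    table$schema[[j]]$bins <- NA_integer_
  }
  table$cutpoints <- utils::modifyList(if (is.null(table$cutpoints)) list() else table$cutpoints, used)
  table
}

#' Does a table still contain raw continuous columns?
#' @param table A `record_table`.
#' @return `TRUE` if any column kind is numeric or date.
#' @export
has_continuous_columns <- function(table) {
  any(schema_kinds(table$schema) %in% c("numeric", "date"))
}
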