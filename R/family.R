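#' Construct a p-value family
#'
#' Bundles the marginal p-values from a set of `m` hypothesis tests together
#' with optional hypothesis labels and the stable ascending sort order used
#' by every step-up and step-down procedure in the package.
#'
#' @param values numeric vector of p-values, each in `[0, 1]`.
#' @param labels optional character vector of hypothesis identifiers, one per
#'   p-value.
#'
#' @return An object of class `"pvalue_family"`: a list with components
#'   `values`, `labels`, `m` (the number of hypotheses) and `order`, the
#'   permutation mapping rank `r` to the original index of the r-th smallest
#'   p-value.  Ties are broken by original position (stable sort).
#'
#' @examples
#' fam <- pvalue_family(c(0.5, 0.01, 0.2))
#' fam$order          # 2 3 1
#' fam$values[fam$order]
#' @export
pvalue_family <- function(values, labels = NULL) {
  values <- as.numeric(values)
  m <- length(values)
  if (m < 1L) stop("a p-value family needs at least one p-value")
  if (anyNA(values)) {
    stop("missing p-value at position ", which(is.na(values))[1L])
  }
  bad <- which(values < 0 | values > 1)
  if (length(bad)) {
    stop("p-value outside [0, 1] at position ", bad[1L], ": ", values[bad[1L]])
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != m) stop("labels must have one entry per p-value")
  }
  structure(
    list(values = values, labels = labels, m = m, order = order(values)),
    class = "pvalue_family"
  )
}

#' @export
print.pvalue_family <- function(x, ...) {
  cat("p-value family: m =", x$m, "hypotheses\n")
  qs <- stats::quantile(x$values, c(0, 0.25, 0.5, 0.75, 1))
  cat("  p-value range:", format(qs[1L], digits = 4), "to",
      format(qs[5L], digits = 4), "\n")
  cat("  quartiles:", paste(format(qs[2:4], digits = 4), collapse = " / "),
      "\n")
  if (!is.null(x$truth)) {
    cat("  known truth: m0 =", x$truth$m0,
        sprintf("(pi0 = %.3f)", x$truth$pi0), "\n")
  }
  invisible(x)
}

#' Ground-truth labels for a simulated p-value family
#'
#' @param is_true_null logical vector; `TRUE` where the null hypothesis is
#'   actually true.
#'
#' @return An object of class `"truth_labels"` with components
#'   `is_true_null`, `m`, `m0` (number of true nulls) and `pi0 = m0/m`.
#' @export
truth_labels <- function(is_true_null) {
  is_true_null <- as.logical(is_true_null)
  if (!length(is_true_null) || anyNA(is_true_null)) {
    stop("is_true_null must be a logical vector without missing values")
  }
  m <- length(is_true_null)
  m0 <- sum(is_true_null)
  structure(
    list(is_true_null = is_true_null, m = m, m0 = m0, pi0 = m0 / m),
    class = "truth_labels"
  )
}

#' Read a p-value family from a text file
#'
#' Accepts either plain text with one p-value per line (an optional single
#' non-numeric header line is skipped) or a delimited table (comma, tab or
#' semicolon, sniffed from the header line) with a named numeric column.
#' A column named `label` (or the first character column), when present,
#' supplies hypothesis labels.
#'
#' @param path file to read.
#' @param column name of the p-value column in a delimited table
#'   (default `"p"`).
#'
#' @return A [pvalue_family].
#' @export
read_pvalues <- function(path, column = "p") {
  if (!file.exists(path)) stop("p-value file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty p-value file: ", path)
  first <- lines[which(keep)[1L]]

  delim <- if (grepl("\t", first, fixed = TRUE)) "\t"
  else if (grepl(",", first, fixed = TRUE)) ","
  else if (grepl(";", first, fixed = TRUE)) ";"
  else NULL

  if (is.null(delim)) {
    body <- trimws(lines[keep])
    lineno <- which(keep)
    vals <- suppressWarnings(as.numeric(body))
    if (is.na(vals[1L]) && length(vals) > 1L) {
      # single header token such as "p"
      body <- body[-1L]
      lineno <- lineno[-1L]
      vals <- suppressWarnings(as.numeric(body))
    }
    if (anyNA(vals)) {
      i <- which(is.na(vals))[1L]
      stop("non-numeric p-value on line ", lineno[i], ": '", body[i], "'")
    }
    return(pvalue_family(vals))
  }

  tab <- utils::read.table(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  if (!column %in% names(tab)) {
    stop("column '", column, "' not found in ", path,
         " (columns: ", paste(names(tab), collapse = ", "), ")")
  }
  raw <- tab[[column]]
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    i <- which(is.na(vals))[1L]
    stop("non-numeric p-value on line ", i + 1L, ": '", raw[i], "'")
  }
  labels <- NULL
  if ("label" %in% names(tab)) {
    labels <- as.character(tab[["label"]])
  } else {
    chr <- vapply(tab, is.character, logical(1L))
    if (any(chr)) labels <- as.character(tab[[which(chr)[1L]]])
  }
  pvalue_family(vals, labels = labels)
}

#' Write a p-value family to CSV
#'
#' Writes columns `label` (when present), `p` and, when the family carries
#' simulation truth, `true_null`.
#'
#' @param family a [pvalue_family].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pvalues <- function(family, path) {
  stopifnot(inherits(family, "pvalue_family"))
  df <- data.frame(p = family$values)
  if (!is.null(family$labels)) df <- cbind(label = family$labels, df)
  if (!is.null(family$truth)) df$true_null <- family$truth$is_true_null
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
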