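#' Ordered age-class schema
#'
#' Age-at-death data are recorded in ordered age classes defined by tooth
#' eruption and wear stages. A schema lists the class boundaries in months;
#' classes are half-open intervals `[lower, upper)`, contiguous and strictly
#' increasing, starting at 0 months. The last (open-ended) archaeological
#' class is closed by an explicit `terminal_cap`, required because the model
#' works with class midpoints.
#'
#' @param lower numeric vector of lower bounds in months; `lower[1]` must be 0.
#' @param upper numeric vector of upper bounds in months; the last entry may
#'   be `NA`, in which case `terminal_cap` is used.
#' @param labels optional character labels, one per class; defaults to
#'   `"lower-upper"`.
#' @param terminal_cap explicit upper bound in months for the last class.
#'   Defaults to the last upper bound if given, otherwise 144.
#'
#' @return An object of class `age_class_schema`: a list with elements
#'   `classes` (data frame `label`, `lower`, `upper`), `terminal_cap` and
#'   `midpoints` (the per-class midpoints t_j in months).
#' @examples
#' legge <- age_class_schema(
#'   lower = c(0, 1, 8, 18, 30, 36, 48, 78, 108),
#'   upper = c(1, 8, 18, 30, 36, 48, 78, 108, 144))
#' class_midpoints(legge)
#' @export
age_class_schema <- function(lower, upper, labels = NULL, terminal_cap = NULL) {
  if (length(lower) != length(upper))
    stop("'lower' and 'upper' must have the same length")
  n <- length(lower)
  if (n < 2L) stop("a schema needs at least 2 age classes")
  if (anyNA(lower)) stop("lower bounds must not be NA")
  if (anyNA(upper[-n])) stop("only the last upper bound may be NA")
  if (is.na(upper[n])) {
    upper[n] <- if (is.null(terminal_cap)) 144 else terminal_cap
  } else if (!is.null(terminal_cap)) {
    if (!isTRUE(all.equal(terminal_cap, upper[n])))
      stop("terminal_cap (", terminal_cap, ") conflicts with the last upper bound (",
           upper[n], ")")
  }
  terminal_cap <- upper[n]
  if (lower[1L] != 0) stop("the first lower bound must be 0 months")
  for (j in seq_len(n)) {
    if (upper[j] <= lower[j])
      stop("class ", j, " has upper bound ", upper[j],
           " <= lower bound ", lower[j])
  }
  if (n > 1L) {
    for (j in seq_len(n - 1L)) {
      if (upper[j] != lower[j + 1L])
        stop("classes ", j, " and ", j + 1L, " are not contiguous: upper ",
             upper[j], " vs lower ", lower[j + 1L],
             if (upper[j] > lower[j + 1L]) " (overlap)" else " (gap)")
    }
  }
  if (is.null(labels)) labels <- paste0(format(lower, trim = TRUE), "-",
                                        format(upper, trim = TRUE))
  labels <- as.character(labels)
  if (length(labels) != n) stop("'labels' must have one entry per class")
  if (anyDuplicated(labels)) stop("class labels must be unique")
  out <- list(
    classes = data.frame(label = labels, lower = as.numeric(lower),
                         upper = as.numeric(upper), stringsAsFactors = FALSE),
    terminal_cap = as.numeric(terminal_cap),
    midpoints = (as.numeric(lower) + as.numeric(upper)) / 2)
  class(out) <- "age_class_schema"
  out
}

#' Number of classes in a schema
#' @param schema an [age_class_schema()].
#' @return integer count of age classes (T*).
#' @export
n_classes <- function(schema) {
  stopifnot(inherits(schema, "age_class_schema"))
  nrow(schema$classes)
}

#' Class midpoints t_j
#' @param schema an [age_class_schema()].
#' @return numeric vector of midpoints in months.
#' @export
class_midpoints <- function(schema) {
  stopifnot(inherits(schema, "age_class_schema"))
  schema$midpoints
}

#' @export
print.age_class_schema <- function(x, ...) {
  cat("Age-class schema:", nrow(x$classes), "classes, terminal cap",
      x$terminal_cap, "months\n")
  df <- x$classes
  df$midpoint <- x$midpoints
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read an age-class schema from a structured text file
#'
#' The file holds one `class: label, lower, upper` line per class (the last
#' upper bound may be empty for an open-ended class) and an optional
#' `terminal_cap: months` line.
#'
#' @param path path to the schema file.
#' @return an [age_class_schema()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cap <- NULL
  labels <- character(); lower <- numeric(); upper <- numeric()
  for (ln in lines) {
    if (grepl("^terminal_cap\\s*:", ln)) {
      cap <- as.numeric(trimws(sub("^terminal_cap\\s*:", "", ln)))
    } else if (grepl("^class\\s*:", ln)) {
      parts <- trimws(strsplit(sub("^class\\s*:", "", ln), ",")[[1L]])
      if (length(parts) < 2L) stop("malformed class line: ", ln)
      if (length(parts) == 2L) parts <- c(parts, NA_character_)
      labels <- c(labels, parts[1L])
      lower <- c(lower, as.numeric(parts[2L]))
      upper <- c(upper, if (is.na(parts[3L]) || !nzchar(parts[3L]))
        NA_real_ else as.numeric(parts[3L]))
    } else {
      stop("unrecognised schema line: ", ln)
    }
  }
  if (length(labels) == 0L) stop("no 'class:' lines found in ", path)
  age_class_schema(lower, upper, labels = labels, terminal_cap = cap)
}

#' Write an age-class schema to a structured text file
#' @param schema an [age_class_schema()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "age_class_schema"))
  df <- schema$classes
  lines <- c(
    sprintf("class: %s, %s, %s", df$label, format(df$lower, trim = TRUE),
            format(df$upper, trim = TRUE)),
    sprintf("terminal_cap: %s", format(schema$terminal_cap, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' The nine-class cattle age schema used throughout the examples
#'
#' Boundaries (months): (0,1), (1,8), (8,18), (18,30), (30,36), (36,48),
#' (48,78), (78,108), (108,144). This is the tooth eruption/wear schema in
#' common use for cattle kill-off profiles.
#' @return an [age_class_schema()].
#' @export
legge_schema <- function() {
  age_class_schema(
    lower = c(0, 1, 8, 18, 30, 36, 48, 78, 108),
    upper = c(1, 8, 18, 30, 36, 48, 78, 108, 144),
    labels = c("0-1", "1-8", "8-18", "18-30", "30-36", "36-48",
               "48-78", "78-108", "108-144"))
}
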