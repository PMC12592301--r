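#' Modern herd census table
#'
#' Survivor counts from censuses of modern unimproved herds: for every herd
#' i, sex s and age class j, the number of animals Y_sij still alive at the
#' class midpoint, together with the herd population size PS_ij used as the
#' Poisson offset. Sex is coded male = 1, female = 0.
#'
#' @param df data frame with columns `herd_id`, `sex` (0/1 or
#'   "female"/"male"), `age_class` (schema labels), `survivors`,
#'   `population`. Exactly one row per (herd, sex, class); all cells must be
#'   present.
#' @param schema an [age_class_schema()].
#' @return An object of class `modern_herd_table`: list with the validated
#'   `data` (sex coded 0/1), `schema`, and `herd_ids`.
#' @export
modern_herd_table <- function(df, schema) {
  stopifnot(inherits(schema, "age_class_schema"))
  need <- c("herd_id", "sex", "age_class", "survivors", "population")
  if (!all(need %in% names(df)))
    stop("table must have columns ", paste(need, collapse = ", "))
  df <- df[need]
  if (is.character(df$sex) || is.factor(df$sex)) {
    sx <- tolower(as.character(df$sex))
    if (!all(sx %in% c("male", "female", "0", "1")))
      stop("sex must be male/female or 1/0")
    df$sex <- ifelse(sx %in% c("male", "1"), 1L, 0L)
  }
  if (!all(df$sex %in% c(0L, 1L))) stop("sex must be coded 0 (female) / 1 (male)")
  labs <- schema$classes$label
  bad <- setdiff(unique(df$age_class), labs)
  if (length(bad))
    stop("age class label(s) not in schema: ", paste(bad, collapse = ", "))
  if (anyNA(df$survivors) || anyNA(df$population))
    stop("missing survivor or population values")
  if (any(df$survivors < 0) || any(df$survivors != round(df$survivors)))
    stop("'survivors' must be non-negative integers")
  if (any(df$population < 1) || any(df$population != round(df$population)))
    stop("'population' must be positive integers")
  if (any(df$survivors > df$population)) {
    i <- which(df$survivors > df$population)[1L]
    stop("survivors (", df$survivors[i], ") exceed population (",
         df$population[i], ") for herd ", df$herd_id[i], ", sex ", df$sex[i],
         ", class ", df$age_class[i])
  }
  key <- paste(df$herd_id, df$sex, df$age_class, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate row for herd ", d$herd_id, ", sex ", d$sex, ", class ",
         d$age_class)
  }
  herds <- unique(df$herd_id)
  expected <- length(herds) * 2L * length(labs)
  if (nrow(df) != expected)
    stop("incomplete table: expected ", expected,
         " rows (herd x sex x class), got ", nrow(df))
  df$survivors <- as.integer(df$survivors)
  df$population <- as.integer(df$population)
  out <- list(data = df, schema = schema, herd_ids = herds)
  class(out) <- "modern_herd_table"
  out
}

#' @export
print.modern_herd_table <- function(x, ...) {
  cat("Modern herd table:", length(x$herd_ids), "herds x 2 sexes x",
      n_classes(x$schema), "classes (", nrow(x$data), "cells )\n")
  invisible(x)
}

#' @export
as.data.frame.modern_herd_table <- function(x, ...) x$data

#' Read a modern herd census table from CSV
#'
#' Columns: `herd_id,sex,age_class,survivors,population`.
#'
#' @param path CSV path.
#' @param schema an [age_class_schema()].
#' @return a [modern_herd_table()].
#' @export
read_modern_table <- function(path, schema) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  modern_herd_table(df, schema)
}

#' Write a modern herd census table to CSV
#' @param table a [modern_herd_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_modern_table <- function(table, path) {
  stopifnot(inherits(table, "modern_herd_table"))
  utils::write.csv(table$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
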