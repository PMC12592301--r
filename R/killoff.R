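#' Ancient kill-off (age-at-death) profile
#'
#' Death counts per age class for one site, derived from MNI estimates.
#' Fragmentary material means some individuals can only be placed in a run
#' of adjacent classes; those are recorded per individual as candidate-class
#' sets and imputed during MCMC rather than split fractionally.
#'
#' @param site_id site identifier (character scalar).
#' @param counts non-negative integer vector of fixed death counts N_kj, one
#'   per schema class.
#' @param schema an [age_class_schema()].
#' @param ambiguous list of integer vectors; each is a contiguous run of at
#'   least two class indices among which one individual may fall.
#' @param .allow_empty allow a profile with zero individuals (used for
#'   prior-predictive runs; ordinary profiles must contain at least one).
#' @return An object of class `killoff_profile`.
#' @examples
#' sch <- legge_schema()
#' killoff_profile("siteA", c(3, 5, 2, 0, 1, 0, 4, 2, 1), sch,
#'                 ambiguous = list(c(7L, 8L)))
#' @export
killoff_profile <- function(site_id, counts, schema, ambiguous = list(),
                            .allow_empty = FALSE) {
  stopifnot(inherits(schema, "age_class_schema"))
  Tstar <- n_classes(schema)
  if (length(counts) != Tstar)
    stop("'counts' must have one entry per age class (", Tstar, ")")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  counts <- as.integer(round(counts))
  if (!is.list(ambiguous)) stop("'ambiguous' must be a list")
  for (set in ambiguous) {
    set <- as.integer(set)
    if (length(set) < 2L)
      stop("each candidate set must contain at least 2 classes")
    if (any(set < 1L) || any(set > Tstar))
      stop("candidate class index out of range")
    if (!identical(sort(set), seq(min(set), max(set))) ||
        length(set) != max(set) - min(set) + 1L)
      stop("candidate set {", paste(set, collapse = ","),
           "} is not a contiguous run of adjacent classes")
  }
  ambiguous <- lapply(ambiguous, function(s) sort(as.integer(s)))
  total <- sum(counts) + length(ambiguous)
  if (total < 1L && !.allow_empty)
    stop("profile contains no individuals")
  out <- list(site_id = as.character(site_id), schema = schema,
              counts = counts, ambiguous = ambiguous)
  class(out) <- "killoff_profile"
  out
}

#' Total individuals in a profile
#' @param profile a [killoff_profile()].
#' @return integer N_k. = sum of fixed counts plus ambiguous individuals.
#' @export
total_individuals <- function(profile) {
  stopifnot(inherits(profile, "killoff_profile"))
  sum(profile$counts) + length(profile$ambiguous)
}

#' @export
print.killoff_profile <- function(x, ...) {
  cat("Kill-off profile '", x$site_id, "': ", total_individuals(x),
      " individuals over ", n_classes(x$schema), " classes (",
      length(x$ambiguous), " with ambiguous age)\n", sep = "")
  df <- data.frame(class = x$schema$classes$label, count = x$counts)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read kill-off profiles from CSV
#'
#' The counts file has columns `site_id,age_class,count`; an optional
#' ambiguity file has columns `site_id,individual_id,candidate_classes`
#' with candidate class labels separated by `;`. Classes absent from the
#' counts file get a zero count.
#'
#' @param path path to the counts CSV.
#' @param schema an [age_class_schema()] whose labels the file must use.
#' @param ambiguity_path optional path to the ambiguity CSV.
#' @return a [killoff_profile()] if the file holds one site, otherwise a
#'   named list of profiles.
#' @export
read_killoff <- function(path, schema, ambiguity_path = NULL) {
  stopifnot(inherits(schema, "age_class_schema"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("site_id", "age_class", "count")
  if (!all(need %in% names(df)))
    stop("counts file must have columns ", paste(need, collapse = ", "))
  labs <- schema$classes$label
  bad <- setdiff(unique(df$age_class), labs)
  if (length(bad))
    stop("age class label(s) not in schema: ", paste(bad, collapse = ", "))
  amb <- NULL
  if (!is.null(ambiguity_path)) {
    amb <- utils::read.csv(ambiguity_path, stringsAsFactors = FALSE,
                           comment.char = "#")
    need2 <- c("site_id", "individual_id", "candidate_classes")
    if (!all(need2 %in% names(amb)))
      stop("ambiguity file must have columns ", paste(need2, collapse = ", "))
  }
  sites <- unique(df$site_id)
  profiles <- lapply(sites, function(sid) {
    sub <- df[df$site_id == sid, , drop = FALSE]
    if (anyDuplicated(sub$age_class))
      stop("duplicate age class rows for site ", sid)
    counts <- integer(length(labs))
    counts[match(sub$age_class, labs)] <- sub$count
    sets <- list()
    if (!is.null(amb)) {
      asub <- amb[amb$site_id == sid, , drop = FALSE]
      sets <- lapply(asub$candidate_classes, function(s) {
        cl <- trimws(strsplit(as.character(s), ";", fixed = TRUE)[[1L]])
        idx <- match(cl, labs)
        if (anyNA(idx))
          stop("ambiguity class label(s) not in schema: ",
               paste(cl[is.na(idx)], collapse = ", "))
        as.integer(idx)
      })
    }
    killoff_profile(sid, counts, schema, ambiguous = sets)
  })
  names(profiles) <- sites
  if (length(profiles) == 1L) profiles[[1L]] else profiles
}

#' Write a kill-off profile to CSV
#' @param profile a [killoff_profile()].
#' @param path output counts CSV path.
#' @param ambiguity_path optional output path for the ambiguity CSV; written
#'   only when the profile has ambiguous individuals and a path is given.
#' @return `path`, invisibly.
#' @export
write_killoff <- function(profile, path, ambiguity_path = NULL) {
  stopifnot(inherits(profile, "killoff_profile"))
  df <- data.frame(site_id = profile$site_id,
                   age_class = profile$schema$classes$label,
                   count = profile$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(ambiguity_path) && length(profile$ambiguous)) {
    labs <- profile$schema$classes$label
    adf <- data.frame(
      site_id = profile$site_id,
      individual_id = seq_along(profile$ambiguous),
      candidate_classes = vapply(profile$ambiguous, function(s)
        paste(labs[s], collapse = ";"), character(1L)))
    utils::write.csv(adf, ambiguity_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
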