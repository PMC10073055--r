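#' @keywords internal
#' Shared error constructors. All package errors carry class "effortdiv_error"
#' plus a subclass so callers (and the CLI) can branch on the failure mode.
stop_schema <- function(msg, ...) {
  abort(msg, class = c("effortdiv_schema_error", "effortdiv_error"), ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = c("effortdiv_validation_error", "effortdiv_error"), ...)
}

haul_table_columns <- c(
  "site_id", "haul_number", "habitat", "haul_length", "haul_depth",
  "species", "count"
)

known_habitats <- c("run", "riffle", "pool", "backwater", "other")

#' Validate a haul-level count table
#'
#' A haul table is a long-format record of seine-haul catches: one row per
#' (site, haul, species) with the haul's metadata repeated on each row. Hauls
#' that caught no fish are kept representable by a sentinel row with `species
#' = NA` and `count = 0`, so cumulative-effort indexing never skips an empty
#' haul.
#'
#' Checks performed:
#' \itemize{
#'   \item required columns present (`site_id`, `haul_number`, `species`,
#'     `count`; `habitat`, `haul_length`, `haul_depth` optional),
#'   \item counts are non-negative integers; lengths/depths positive where
#'     present,
#'   \item haul numbers within each site form a contiguous `1..K` sequence,
#'   \item no duplicated (site, haul, species) combination,
#'   \item haul metadata (habitat, length, depth) constant within a haul.
#' }
#'
#' @param x A data frame of haul-level counts.
#' @return `x` as a tibble, invisibly validated (row order preserved).
#' @examples
#' tbl <- tibble::tibble(
#'   site_id = "s1", haul_number = c(1L, 2L, 2L),
#'   species = c("a", "a", "b"), count = c(2L, 1L, 1L)
#' )
#' validate_haul_table(tbl)
#' @export
validate_haul_table <- function(x) {
  if (!is.data.frame(x)) {
    stop_schema("haul table must be a data frame")
  }
  x <- tibble::as_tibble(x)
  required <- c("site_id", "haul_number", "species", "count")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "haul table is missing required column%s: %s",
      if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), missing_columns = missing)
  }

  if (!is.numeric(x$haul_number) || any(is.na(x$haul_number)) ||
      any(x$haul_number != as.integer(x$haul_number)) || any(x$haul_number < 1)) {
    stop_validation("haul_number must be an integer >= 1 for every row")
  }
  x$haul_number <- as.integer(x$haul_number)

  bad_count <- which(is.na(x$count) | !is.numeric(x$count) |
                       x$count < 0 | x$count != round(x$count))
  if (!is.numeric(x$count)) bad_count <- seq_len(nrow(x))
  if (length(bad_count) > 0) {
    stop_validation(
      sprintf("count must be a non-negative integer (first bad row: %d)",
              bad_count[1]),
      rows = bad_count
    )
  }
  x$count <- as.integer(x$count)

  for (col in c("haul_length", "haul_depth")) {
    if (col %in% names(x)) {
      vals <- x[[col]]
      if (any(!is.na(vals) & vals <= 0)) {
        stop_validation(sprintf("%s must be > 0 where present", col))
      }
    }
  }

  if ("habitat" %in% names(x)) {
    bad_hab <- setdiff(unique(x$habitat[!is.na(x$habitat)]), known_habitats)
    if (length(bad_hab) > 0) {
      stop_validation(sprintf(
        "unknown habitat class(es): %s (expected %s)",
        paste(bad_hab, collapse = ", "), paste(known_habitats, collapse = ", ")
      ))
    }
  }

  # sentinel rows: species NA must carry count 0
  sentinel <- is.na(x$species)
  if (any(x$count[sentinel] != 0L)) {
    stop_validation("rows with species = NA are empty-haul sentinels and must have count = 0")
  }

  # contiguity of haul numbers per site
  hauls_by_site <- split(x$haul_number, x$site_id)
  for (s in names(hauls_by_site)) {
    ks <- sort(unique(hauls_by_site[[s]]))
    if (!identical(ks, seq_len(max(ks)))) {
      stop_validation(sprintf(
        "site '%s': haul numbers are not a contiguous 1..K sequence (empty hauls need a sentinel row)",
        s
      ))
    }
  }

  # duplicate (site, haul, species) among real species rows
  real <- x[!sentinel, , drop = FALSE]
  key <- paste(real$site_id, real$haul_number, real$species, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    parts <- strsplit(dup, "\r", fixed = TRUE)[[1]]
    stop_validation(sprintf(
      "duplicated (site, haul, species) combination: (%s, %s, %s)",
      parts[1], parts[2], parts[3]
    ))
  }

  # metadata constant within (site, haul)
  meta_cols <- intersect(c("habitat", "haul_length", "haul_depth"), names(x))
  if (length(meta_cols) > 0) {
    hk <- paste(x$site_id, x$haul_number, sep = "\r")
    for (col in meta_cols) {
      n_distinct_meta <- tapply(x[[col]], hk, function(v) length(unique(v)))
      if (any(n_distinct_meta > 1)) {
        stop_validation(sprintf("%s differs between rows of the same haul", col))
      }
    }
  }

  x
}

#' Read a haul-level count table from delimited text
#'
#' Reads a long-format CSV (one row per site, haul, species) and validates it.
#' Collector order is preserved exactly as recorded: rows are ordered only by
#' site and haul number, never re-sorted by catch.
#'
#' @param path Path to a delimited text file.
#' @param dialect Optional dialect description: either a list with elements
#'   `delim` (field delimiter, default ",") and `columns` (named character
#'   vector mapping canonical names, e.g. `c(site_id = "Station")`, to the
#'   file's headers), or the path to a YAML file holding the same structure.
#' @return A validated haul-table tibble.
#' @seealso [write_haul_table()], [validate_haul_table()]
#' @export
read_haul_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    stop_schema(sprintf("file not found: %s", path))
  }
  dialect <- resolve_dialect(dialect)
  raw <- readr::read_delim(path, delim = dialect$delim, show_col_types = FALSE,
                           progress = FALSE)
  if (length(dialect$columns) > 0) {
    for (canonical in names(dialect$columns)) {
      from <- dialect$columns[[canonical]]
      if (!from %in% names(raw)) {
        stop_schema(sprintf("mapped column '%s' (for %s) not found in %s",
                            from, canonical, path))
      }
      names(raw)[names(raw) == from] <- canonical
    }
  }
  missing <- setdiff(c("site_id", "haul_number", "species", "count"), names(raw))
  if (length(missing) > 0) {
    stop_schema(sprintf("%s is missing required column%s: %s", path,
                        if (length(missing) > 1) "s" else "",
                        paste(missing, collapse = ", ")),
                missing_columns = missing)
  }
  raw$site_id <- as.character(raw$site_id)
  if ("species" %in% names(raw)) raw$species <- as.character(raw$species)
  out <- validate_haul_table(raw)
  dplyr::arrange(out, .data$site_id, .data$haul_number)
}

#' Write a haul-level count table to delimited text
#'
#' Inverse of [read_haul_table()]: the written file round-trips bit-exactly
#' for identifiers and integer counts.
#'
#' @inheritParams read_haul_table
#' @param x A validated haul table.
#' @return `path`, invisibly.
#' @export
write_haul_table <- function(x, path, dialect = NULL) {
  x <- validate_haul_table(x)
  dialect <- resolve_dialect(dialect)
  out <- x
  if (length(dialect$columns) > 0) {
    for (canonical in names(dialect$columns)) {
      names(out)[names(out) == canonical] <- dialect$columns[[canonical]]
    }
  }
  readr::write_delim(out, path, delim = dialect$delim)
  invisible(path)
}

resolve_dialect <- function(dialect) {
  if (is.null(dialect)) {
    return(list(delim = ",", columns = character()))
  }
  if (is.character(dialect) && length(dialect) == 1) {
    if (!file.exists(dialect)) {
      stop_schema(sprintf("dialect file not found: %s", dialect))
    }
    dialect <- yaml::read_yaml(dialect)
  }
  if (!is.list(dialect)) {
    stop_schema("dialect must be NULL, a list, or a YAML file path")
  }
  delim <- dialect$delim %||% ","
  columns <- unlist(dialect$columns %||% character())
  list(delim = delim, columns = columns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pool counts over the first k hauls of a site
#'
#' Sums species counts over hauls `1..k` at one site, in collector order.
#' This is the cumulative-effort pooling that all accumulation curves are
#' built on: the abundance vector at effort `k`.
#'
#' @param x A validated haul table.
#' @param site_id Site identifier present in `x`.
#' @param k Number of consecutive hauls to pool (`1 <= k <= K`).
#' @return A named integer vector of per-species counts (species with zero
#'   pooled count are absent). Empty hauls contribute nothing; pooling only
#'   empty hauls gives a zero-length vector.
#' @examples
#' tbl <- tibble::tibble(
#'   site_id = "s1", haul_number = c(1L, 2L, 2L),
#'   species = c("a", "a", "b"), count = c(2L, 1L, 1L)
#' )
#' pool_counts(tbl, "s1", 2)  # a = 3, b = 1
#' @export
pool_counts <- function(x, site_id, k) {
  x <- validate_haul_table(x)
  rows <- x[x$site_id == site_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_validation(sprintf("unknown site_id: '%s'", site_id))
  }
  kmax <- max(rows$haul_number)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > kmax || k != round(k)) {
    stop_validation(sprintf(
      "k must be a single integer in [1, %d] for site '%s'", kmax, site_id
    ))
  }
  rows <- rows[rows$haul_number <= k & !is.na(rows$species) & rows$count > 0, ,
               drop = FALSE]
  if (nrow(rows) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  sums <- tapply(rows$count, rows$species, sum)
  out <- as.integer(sums)
  names(out) <- names(sums)
  out[order(names(out))]
}

#' Summarise an abundance vector
#'
#' Reports the quantities the nonparametric richness machinery runs on:
#' total abundance `n`, observed richness `s_obs`, and the singleton (`f1`)
#' and doubleton (`f2`) counts.
#'
#' @param x Named numeric vector of species counts.
#' @return One-row tibble with columns `n`, `s_obs`, `f1`, `f2`.
#' @export
abundance_summary <- function(x) {
  x <- check_abundance(x)
  tibble::tibble(
    n = sum(x),
    s_obs = sum(x > 0),
    f1 = sum(x == 1),
    f2 = sum(x == 2)
  )
}

# coerce/validate an abundance vector: non-negative integer counts
check_abundance <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("species", "count") %in% names(x))) {
      stop_schema("abundance data frame needs 'species' and 'count' columns")
    }
    x <- stats::setNames(x$count, x$species)
  }
  if (length(x) == 0) return(stats::setNames(integer(0), character(0)))
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop_validation("abundances must be non-negative integer counts")
  }
  x
}

# Set the RNG seed for the calling function's scope and restore the previous
# global RNG state on exit, so seeded package utilities never perturb the
# caller's random stream.
local_rng <- function(seed, envir = parent.frame()) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  withr::defer({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, envir = envir)
  set.seed(as.integer(seed))
}
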