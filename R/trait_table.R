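#' Default morphological trait schema
#'
#' The five fern morphotraits used throughout the package, with their
#' measurement scales and coded domains: rhizome type (categorical, codes
#' 0--3), laminar dissection (ordinal, 0--2), laminar texture (ordinal,
#' 1--3), laminar length (continuous, cm, > 0) and hydathodes (binary,
#' 0/1).
#'
#' @return A named list, one element per trait, each a list with elements
#'   `scale` (one of `"categorical"`, `"ordinal"`, `"binary"`,
#'   `"continuous"`) and `domain` (allowed codes, or a numeric range for
#'   continuous traits).
#' @export
default_trait_schema <- function() {
  list(
    rhizome_type      = list(scale = "categorical", domain = 0:3),
    laminar_dissection = list(scale = "ordinal",    domain = 0:2),
    laminar_texture   = list(scale = "ordinal",     domain = 1:3),
    laminar_length    = list(scale = "continuous",  domain = c(0, Inf)),
    hydathodes        = list(scale = "binary",      domain = 0:1)
  )
}

valid_scales <- c("categorical", "ordinal", "binary", "continuous")

#' Construct and validate a species-by-trait table
#'
#' @param traits data.frame of trait values, one row per species, columns
#'   named as in `schema`.
#' @param species_ids character vector of unique species identifiers; by
#'   default taken from `rownames(traits)`.
#' @param schema trait schema as returned by [default_trait_schema()]; each
#'   element declares the trait's measurement scale and domain.
#' @return An object of class `trait_table`: the trait data.frame with
#'   species ids as row names and the schema attached as attribute
#'   `"schema"`.
#' @export
trait_table <- function(traits, species_ids = rownames(traits),
                        schema = default_trait_schema()) {
  traits <- as.data.frame(traits)
  if (is.null(species_ids))
    stop("species_ids are required (row names or explicit vector)")
  species_ids <- as.character(species_ids)
  if (length(species_ids) != nrow(traits))
    stop("species_ids length does not match the number of rows")
  dup <- species_ids[duplicated(species_ids)]
  if (length(dup))
    stop("duplicated species ids: ", paste(unique(dup), collapse = ", "))
  missing_cols <- setdiff(names(schema), names(traits))
  if (length(missing_cols))
    stop("missing trait columns: ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(traits), names(schema))
  if (length(unknown))
    stop("unknown trait columns: ", paste(unknown, collapse = ", "))
  traits <- traits[names(schema)]
  for (tr in names(schema)) {
    sc <- schema[[tr]]$scale
    if (is.null(sc) || !sc %in% valid_scales)
      stop("trait '", tr, "' has no valid scale tag")
    x <- traits[[tr]]
    if (anyNA(x)) {
      bad <- species_ids[is.na(x)]
      stop("missing value for trait '", tr, "' in species: ",
           paste(head(bad, 5), collapse = ", "))
    }
    if (!is.numeric(x))
      stop("trait '", tr, "' must be numerically coded")
    dom <- schema[[tr]]$domain
    if (sc == "continuous") {
      bad <- species_ids[x <= dom[1] | x > dom[2]]
    } else {
      bad <- species_ids[!x %in% dom]
    }
    if (length(bad))
      stop("value outside declared domain for trait '", tr,
           "' in species: ", paste(head(bad, 5), collapse = ", "))
  }
  rownames(traits) <- species_ids
  structure(traits, schema = schema, class = c("trait_table", "data.frame"))
}

#' @export
print.trait_table <- function(x, ...) {
  schema <- attr(x, "schema")
  cat("Trait table:", nrow(x), "species,", length(schema), "traits\n")
  scales <- vapply(schema, function(s) s$scale, "")
  cat("  scales:", paste(names(schema), scales, sep = "=", collapse = ", "),
      "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a species-by-trait table from CSV/TSV
#'
#' The file must have one row per species with a `species` column (or
#' species ids as the first column) and one column per trait named as in
#' the schema.  Values are validated against each trait's declared domain;
#' offending species and traits are named in the error.
#'
#' @param path file path (CSV, or TSV when `sep = "\t"`).
#' @param schema trait schema, see [default_trait_schema()]; alternatively
#'   a path to a schema file readable by [read_trait_schema()].
#' @param sep field separator.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, schema = default_trait_schema(),
                             sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1)
    schema <- read_trait_schema(schema)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  idcol <- if ("species" %in% names(df)) "species" else names(df)[1]
  ids <- as.character(df[[idcol]])
  df[[idcol]] <- NULL
  trait_table(df, species_ids = ids, schema = schema)
}

#' Write a trait table to CSV/TSV
#'
#' @param x a [trait_table()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path, sep = ",") {
  df <- cbind(species = rownames(x), as.data.frame(x))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trait schema from a flat key-value file
#'
#' Each non-empty, non-comment line declares one trait as
#' `name: scale` (e.g. `laminar_texture: ordinal`).  Domains for the five
#' standard traits are filled from [default_trait_schema()]; other
#' categorical/ordinal/binary traits get an unrestricted integer domain and
#' continuous traits the positive reals.
#'
#' @param path file path.
#' @return A schema list as used by [trait_table()].
#' @export
read_trait_schema <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- default_trait_schema()
  schema <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed schema line: ", ln)
    key <- trimws(kv[1]); sc <- trimws(kv[2])
    if (!sc %in% valid_scales)
      stop("unknown scale '", sc, "' for trait '", key, "'")
    if (!is.null(defaults[[key]]) && defaults[[key]]$scale == sc) {
      schema[[key]] <- defaults[[key]]
    } else if (sc == "continuous") {
      schema[[key]] <- list(scale = sc, domain = c(0, Inf))
    } else if (sc == "binary") {
      schema[[key]] <- list(scale = sc, domain = 0:1)
    } else {
      schema[[key]] <- list(scale = sc, domain = 0:100)
    }
  }
  schema
}
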