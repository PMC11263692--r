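# Reading, validation and preprocessing of species trait tables.

.trait_cols <- c("species", "taxon_class", "body_mass", "sperm_length",
                 "clutch_size", "testes_mass", "genome_size")
.required_cols <- c("species", "taxon_class", "body_mass", "sperm_length")
.na_tokens <- c("", "NA", "NaN", "N/A", "na", "nan")

#' Read a species trait table
#'
#' Reads a delimited text file with one row per species and at least the
#' columns species name, taxonomic class, body mass (g) and sperm length
#' (um).  Optional columns: clutch/litter size, testes mass (g), genome
#' size, and per-species `thermoregulation` / `fertilization` overrides.
#' Rows lacking body mass or sperm length, or with non-positive values,
#' are dropped with a logged count; duplicate species names are an error.
#'
#' @param path Path to a CSV/TSV file with a header row (UTF-8).
#' @param column_map Named character vector binding canonical names
#'   (`species`, `taxon_class`, `body_mass`, `sperm_length`, `clutch_size`,
#'   `testes_mass`, `genome_size`) to the file's column headers, so
#'   arbitrary deposits can be read without editing code.  Defaults to the
#'   canonical names themselves.
#' @param sep Field separator; inferred from the file extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @return A `data.frame` of class `trait_table` with canonical columns;
#'   attribute `n_dropped` records how many rows were removed.
#' @export
read_trait_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           na.strings = .na_tokens, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8",
                           colClasses = "character")
  map <- setNames(.trait_cols, .trait_cols)
  if (!"taxon_class" %in% names(raw) && "class" %in% names(raw))
    map["taxon_class"] <- "class"
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing_req <- .required_cols[!map[.required_cols] %in% names(raw)]
  if (length(missing_req))
    stop("missing required column(s): ",
         paste(map[missing_req], collapse = ", "))
  tab <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    species = trimws(raw[[map["species"]]]),
                    taxon_class = trimws(raw[[map["taxon_class"]]]))
  for (col in setdiff(.trait_cols, c("species", "taxon_class"))) {
    src <- map[col]
    if (src %in% names(raw)) {
      val <- raw[[src]]
      num <- suppressWarnings(as.numeric(val))
      bad <- which(!is.na(val) & is.na(num))
      if (length(bad))
        warning(sprintf("column '%s': non-numeric value in row(s) %s set to missing",
                        src, paste(bad, collapse = ", ")))
      tab[[col]] <- num
    } else {
      tab[[col]] <- NA_real_
    }
  }
  for (col in c("thermoregulation", "fertilization"))
    if (col %in% names(raw)) tab[[col]] <- trimws(raw[[col]])

  keep <- is.finite(tab$body_mass) & is.finite(tab$sperm_length)
  nonpos <- keep & (tab$body_mass <= 0 | tab$sperm_length <= 0)
  if (any(nonpos)) {
    warning(sum(nonpos), " row(s) with non-positive body mass or sperm length rejected")
    keep <- keep & !nonpos
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) dropped (missing or invalid body mass / sperm length)")
  tab <- tab[keep, , drop = FALSE]
  dup <- duplicated(tolower(tab$species))
  if (any(dup))
    stop("duplicate species after normalization: ",
         paste(unique(tab$species[dup]), collapse = ", "))
  rownames(tab) <- NULL
  structure(tab, n_dropped = n_dropped, class = c("trait_table", "data.frame"))
}

#' Add log10-transformed body mass and sperm length
#'
#' @param table A trait table.
#' @return The table with `log10_body_mass` and `log10_sperm_length` added.
#' @export
log10_traits <- function(table) {
  if (any(table$body_mass <= 0 | table$sperm_length <= 0, na.rm = TRUE))
    stop("non-positive body mass or sperm length; filter rows first")
  table$log10_body_mass <- log10(table$body_mass)
  table$log10_sperm_length <- log10(table$sperm_length)
  table
}

#' Relative testes mass (within-class log-log regression residuals)
#'
#' For each taxonomic class independently, regresses log10 testes mass on
#' log10 body mass by ordinary least squares and stores the residuals as
#' `rel_testes_mass`, the standard comparative proxy for sperm competition
#' intensity.  Classes with fewer than 3 species with testes data, or with
#' no body-mass variation, yield missing residuals with a warning.
#'
#' @param table A trait table with positive `body_mass` and (optionally)
#'   `testes_mass`.
#' @return The table with a `rel_testes_mass` column.
#' @export
relative_testes_mass <- function(table) {
  table$rel_testes_mass <- NA_real_
  for (cl in unique(table$taxon_class)) {
    in_cl <- table$taxon_class == cl
    has <- in_cl & is.finite(table$testes_mass) & table$testes_mass > 0 &
      is.finite(table$body_mass) & table$body_mass > 0
    if (sum(has) < 3L) {
      if (any(in_cl & is.finite(table$testes_mass)))
        warning("class '", cl, "': fewer than 3 testes-mass records, residuals set missing")
      next
    }
    x <- log10(table$body_mass[has])
    y <- log10(table$testes_mass[has])
    if (stats::var(x) <= 0) {
      warning("class '", cl, "': no body-mass variation, residuals set missing")
      next
    }
    fit <- stats::lm(y ~ x)
    table$rel_testes_mass[has] <- stats::residuals(fit)
  }
  table
}

#' Within-class z-scores of clutch/litter size
#'
#' Normalises clutch/litter size across classes by centring and scaling
#' within each class (sample SD).  Classes with fewer than 2 values or
#' zero SD yield missing z-scores with a warning.
#'
#' @param table A trait table with an optional `clutch_size` column.
#' @return The table with a `clutch_z` column.
#' @export
clutch_zscore <- function(table) {
  table$clutch_z <- NA_real_
  for (cl in unique(table$taxon_class)) {
    has <- table$taxon_class == cl & is.finite(table$clutch_size)
    if (sum(has) < 2L) {
      if (any(has)) warning("class '", cl, "': fewer than 2 clutch values, z set missing")
      next
    }
    s <- stats::sd(table$clutch_size[has])
    if (s <= 0) {
      warning("class '", cl, "': zero clutch-size SD, z set missing")
      next
    }
    table$clutch_z[has] <- (table$clutch_size[has] - mean(table$clutch_size[has])) / s
  }
  table
}

#' Preprocess a trait table for analysis
#'
#' Convenience wrapper: [log10_traits()], [relative_testes_mass()] and
#' [clutch_zscore()] in sequence.
#'
#' @param table A trait table.
#' @return The analysis-ready table.
#' @export
preprocess_trait_table <- function(table) {
  clutch_zscore(relative_testes_mass(log10_traits(table)))
}

.default_subgroups <- list(
  thermoregulation = list(endotherm = c("Aves", "Mammalia"),
                          ectotherm = c("Amphibia", "Reptilia")),
  fertilization = list(internal = c("Aves", "Mammalia", "Reptilia"),
                       external = c("Amphibia"))
)

#' Filter a trait table to a subgroup
#'
#' Subgroups are defined by taxonomic class, thermoregulation mode
#' (endotherm = Aves + Mammalia) or fertilization mode (internal = Aves +
#' Mammalia + Reptilia, external = Amphibia).  Per-species values in
#' optional `thermoregulation` / `fertilization` columns override the
#' class-based mapping.
#'
#' @param table A trait table.
#' @param scheme One of `"class"`, `"thermoregulation"`, `"fertilization"`.
#' @param level The subgroup label to keep.
#' @return The filtered trait table.
#' @export
subgroup <- function(table, scheme = c("class", "thermoregulation", "fertilization"),
                     level) {
  scheme <- match.arg(scheme)
  if (scheme == "class") {
    valid <- unique(table$taxon_class)
    if (!level %in% valid)
      stop("unknown class '", level, "'; valid levels: ", paste(valid, collapse = ", "))
    return(table[table$taxon_class == level, , drop = FALSE])
  }
  mapping <- .default_subgroups[[scheme]]
  if (!level %in% names(mapping))
    stop("unknown ", scheme, " level '", level, "'; valid levels: ",
         paste(names(mapping), collapse = ", "))
  member <- table$taxon_class %in% mapping[[level]]
  if (scheme %in% names(table)) {
    override <- !is.na(table[[scheme]])
    member[override] <- table[[scheme]][override] == level
  }
  table[member, , drop = FALSE]
}

#' Write an analysis-ready trait table as TSV
#'
#' @param table A trait table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
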