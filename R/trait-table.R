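#' Read an individual-level specimen volume table
#'
#' Parses a CSV/TSV file with one specimen per row: a species column, a
#' specimen id, one column per brain structure (volumes in cc) and a
#' hemisphere volume column. Missing cells may be written as an en dash
#' ("–", as printed in published tables), "-", "", or "NA"; they are
#' kept as `NA`, never coerced to zero.
#'
#' @param path file to read.
#' @param structures character vector naming the structure volume columns.
#'   Default: every column except the species, specimen and hemisphere
#'   columns.
#' @param species_col,specimen_col,hemisphere_col column names in the file.
#'   `hemisphere_col = NULL` (or an absent column) is allowed; the
#'   hemisphere column is then created empty.
#' @param laterality named character vector mapping structure names to
#'   `"unilateral"` (value is one hemisphere, used as-is) or
#'   `"bilateral_sum"` (value is the sum over both hemispheres and is halved
#'   once during aggregation). Structures not named default to
#'   `"unilateral"`.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return an `individual_table`: a data.frame with columns `species`,
#'   `specimen_id`, one numeric column per structure, and `hemisphere`,
#'   carrying the laterality map as an attribute.
#' @export
#' @examples
#' tab <- read_trait_table(allodev_example("tables/table1_hominoid_subcortical.csv"))
#' nrow(tab)                      # 20 specimens
#' length(unique(tab$species))    # 8 taxa
read_trait_table <- function(path, structures = NULL,
                             species_col = "species",
                             specimen_col = "specimen_id",
                             hemisphere_col = "hemisphere",
                             laterality = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  for (col in c(species_col, specimen_col)) {
    if (!col %in% names(raw)) {
      stop("declared column '", col, "' not present in ", path, call. = FALSE)
    }
  }
  has_hemi <- !is.null(hemisphere_col) && hemisphere_col %in% names(raw)
  if (is.null(structures)) {
    structures <- setdiff(names(raw),
                          c(species_col, specimen_col, hemisphere_col))
  } else if (!all(structures %in% names(raw))) {
    stop("declared structure column(s) missing: ",
         paste(setdiff(structures, names(raw)), collapse = ", "),
         call. = FALSE)
  }

  missing_symbols <- c("–", "-", "", "NA", "na")
  parse_vol <- function(v, what) {
    v <- trimws(v)
    v[v %in% missing_symbols] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(out)
    if (any(bad)) {
      stop("non-numeric ", what, " value '", v[which(bad)[1]], "' in row ",
           which(bad)[1], call. = FALSE)
    }
    out
  }

  tab <- data.frame(species = trimws(raw[[species_col]]),
                    specimen_id = trimws(raw[[specimen_col]]),
                    stringsAsFactors = FALSE)
  for (s in structures) tab[[s]] <- parse_vol(raw[[s]], s)
  tab$hemisphere <- if (has_hemi) parse_vol(raw[[hemisphere_col]], "hemisphere")
                    else rep(NA_real_, nrow(raw))

  validate_individual_table(tab, structures, laterality)
}

#' Construct and validate an individual-level table from a data.frame
#'
#' @param tab data.frame with `species`, `specimen_id`, structure columns
#'   and `hemisphere`.
#' @param structures structure column names.
#' @param laterality see [read_trait_table()].
#' @return an `individual_table`.
#' @export
validate_individual_table <- function(tab, structures = NULL,
                                      laterality = NULL) {
  if (is.null(structures)) {
    structures <- attr(tab, "structures")
    if (is.null(structures)) {
      structures <- setdiff(names(tab), c("species", "specimen_id", "hemisphere"))
    }
  }
  if (nrow(tab) == 0L) stop("empty specimen table", call. = FALSE)
  if (any(is.na(tab$species) | tab$species == "")) {
    stop("empty species name in row ",
         which(is.na(tab$species) | tab$species == "")[1], call. = FALSE)
  }
  key <- paste(tab$species, tab$specimen_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (species, specimen_id) pair: ",
         sub("\r", " / ", key[duplicated(key)][1]), call. = FALSE)
  }
  for (s in c(structures, "hemisphere")) {
    v <- tab[[s]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      stop("non-positive volume for '", s, "' in row ", which(bad)[1],
           " (species ", tab$species[which(bad)[1]], ")", call. = FALSE)
    }
  }
  lat <- setNames(rep("unilateral", length(structures)), structures)
  if (!is.null(laterality)) {
    unknown <- setdiff(laterality, c("unilateral", "bilateral_sum"))
    if (length(unknown)) {
      stop("unknown laterality code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    extra <- setdiff(names(laterality), structures)
    if (length(extra)) {
      stop("laterality given for unknown structure(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    lat[names(laterality)] <- laterality
  }
  attr(tab, "structures") <- structures
  attr(tab, "laterality") <- lat
  class(tab) <- c("individual_table", "data.frame")
  tab
}

#' Aggregate specimens to species means
#'
#' Collapses an individual-level table to one row per species. Structures
#' flagged `bilateral_sum` are halved per individual before averaging, so
#' halving is applied exactly once; unilateral values are averaged
#' directly. Species means are unweighted arithmetic means of the
#' contributing individuals, and the number of individuals per structure is
#' recorded. A species with no data for a structure gets `NA` there.
#'
#' @param tab an `individual_table`.
#' @return a `species_trait_table`: data.frame with `species`, one mean
#'   column per structure, `hemisphere`, and `n_<structure>` counts.
#' @export
#' @examples
#' tab <- read_trait_table(allodev_example("tables/table1_hominoid_subcortical.csv"))
#' sp <- aggregate_species_means(tab)
#' sp$striatum[sp$species == "Homo sapiens"]  # mean of 9.551 and 12.223
aggregate_species_means <- function(tab) {
  if (!inherits(tab, "individual_table")) {
    tab <- validate_individual_table(tab)
  }
  if (nrow(tab) == 0L) stop("empty specimen table", call. = FALSE)
  structures <- attr(tab, "structures")
  lat <- attr(tab, "laterality")
  species <- unique(tab$species)
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  for (s in c(structures, "hemisphere")) {
    v <- tab[[s]]
    if (!identical(s, "hemisphere") && lat[[s]] == "bilateral_sum") {
      v <- v / 2
    }
    means <- vapply(species, function(sp) {
      vals <- v[tab$species == sp]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) NA_real_ else mean(vals)
    }, numeric(1))
    ns <- vapply(species, function(sp) {
      sum(!is.na(v[tab$species == sp]))
    }, integer(1))
    out[[s]] <- unname(means)
    out[[paste0("n_", s)]] <- unname(ns)
  }
  attr(out, "structures") <- structures
  class(out) <- c("species_trait_table", "data.frame")
  out
}

#' Write / read a species-level trait table
#'
#' Plain CSV round-trip for [aggregate_species_means()] output; values are
#' written with full double precision so a read-back reproduces them
#' exactly.
#'
#' @param x a `species_trait_table`.
#' @param path file path.
#' @return `write_species_table` returns `path` invisibly;
#'   `read_species_table` returns a `species_trait_table`.
#' @export
write_species_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE)
    }, character(1))
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_species_table
#' @export
read_species_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 fileEncoding = "UTF-8")
  structures <- setdiff(names(df), c("species", "hemisphere",
                                     grep("^n_", names(df), value = TRUE)))
  attr(df, "structures") <- structures
  class(df) <- c("species_trait_table", "data.frame")
  df
}

#' Cavalieri point-count volume estimate
#'
#' The stereological volume estimator from systematically spaced sections:
#' total points counted times the grid area represented by one point times
#' the spacing between sections, converted from cubic micrometres to cc
#' (1 cc = 1e12 um^3).
#'
#' @param points_counted total number of grid points hitting the structure.
#' @param grid_area_per_point area represented by one grid point (um^2).
#' @param section_spacing distance between measured sections (um).
#' @return volume in cc.
#' @export
#' @examples
#' cavalieri_volume(1000, 150, 1000)  # 1.5e-4 cc
cavalieri_volume <- function(points_counted, grid_area_per_point,
                             section_spacing) {
  for (v in list(points_counted, grid_area_per_point, section_spacing)) {
    if (!is.numeric(v) || any(is.na(v)) || any(v <= 0)) {
      stop("all Cavalieri parameters must be strictly positive", call. = FALSE)
    }
  }
  points_counted * grid_area_per_point * section_spacing / 1e12
}
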