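#' Build an analysis-ready species-by-trait table from per-record means
#'
#' Applies the study inclusion filters in a fixed, documented order and
#' log10-transforms everything that survives:
#'
#' 1. rows are restricted to female values (`sex_mode = "strict"` drops rows
#'    with unrecorded sex; `"permissive"` keeps them);
#' 2. cells based on fewer than `min_animals` animals are dropped;
#' 3. traits left with fewer than `min_species` species are dropped entirely
#'    (so a trait can be lost solely because the animal filter thinned it);
#' 4. remaining per-species records of a trait are combined as an
#'    n-weighted mean, then log10-transformed.
#'
#' Body mass (`trait == "mass"`) goes through the same filters; a species
#' without a surviving mass value is excluded from the table, because mass is
#' the mandatory predictor in every downstream model. The target species
#' enters through `target_values` (native scale, already midpointed), not
#' through `records`, so the captive-population filters never apply to it.
#'
#' @param records Data frame with columns `species`, `trait`, `sex`, `value`
#'   (native units, must be positive so log10 is defined) and `n`
#'   (number of animals behind the mean).
#' @param target_values Named numeric vector or list mapping trait name to
#'   the target species' native-scale value; must include `"mass"`.
#' @param target_species Label for the appended target row.
#' @param min_animals Minimum animals per cell (default 10).
#' @param min_species Minimum species per retained trait (default 10).
#' @param sex_mode `"strict"` (default) or `"permissive"`, see above.
#' @return A `trait_table`: a data frame with columns `species`, `mass` and
#'   one column per surviving trait (all log10), with attributes `target`
#'   (the target species label) and `audit` (per-trait filter decisions).
#' @export
build_table <- function(records, target_values, target_species = "target",
                        min_animals = 10, min_species = 10,
                        sex_mode = c("strict", "permissive")) {
  sex_mode <- match.arg(sex_mode)
  req <- c("species", "trait", "sex", "value", "n")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(records) == 0) stop("records is empty")
  records$species <- normalize_label(records$species)
  records$trait <- as.character(records$trait)
  if (any(records$n < 1)) stop("n_animals must be >= 1 for every record")
  bad <- !is.finite(records$value) | records$value <= 0
  if (any(bad)) {
    b <- records[bad, ][1, ]
    stop("non-positive or non-finite value for species ", b$species,
         ", trait ", b$trait, " (log10 undefined)")
  }

  audit <- list()
  n0 <- table(records$trait)

  sex <- tolower(trimws(as.character(records$sex)))
  keep_sex <- if (sex_mode == "strict") {
    !is.na(sex) & sex %in% c("f", "female")
  } else {
    is.na(sex) | sex %in% c("f", "female", "", "u", "unknown")
  }
  recs <- records[keep_sex, , drop = FALSE]

  recs <- recs[recs$n >= min_animals, , drop = FALSE]
  if (nrow(recs) == 0) stop("no records survive the sex and animal filters")

  # species-count filter per trait (after the animal filter, by design)
  sp_per_trait <- tapply(recs$species, recs$trait,
                         function(s) length(unique(s)))
  keep_traits <- names(sp_per_trait)[sp_per_trait >= min_species]
  for (tr in names(n0)) {
    audit[[tr]] <- list(
      records_in = as.integer(n0[[tr]]),
      records_after_filters = sum(recs$trait == tr),
      species_after_filters = if (tr %in% names(sp_per_trait))
        as.integer(sp_per_trait[[tr]]) else 0L,
      kept = tr %in% keep_traits
    )
  }
  recs <- recs[recs$trait %in% keep_traits, , drop = FALSE]
  if (nrow(recs) == 0) stop("no traits survive the species-count filter")
  if (!"mass" %in% recs$trait) {
    stop("no qualifying body-mass records; mass is the mandatory predictor")
  }

  # n-weighted species x trait means, then log10
  agg <- stats::aggregate(
    cbind(wv = recs$value * recs$n, w = recs$n),
    by = list(species = recs$species, trait = recs$trait), FUN = sum)
  agg$value <- log10(agg$wv / agg$w)

  species <- sort(unique(agg$species))
  traits <- sort(setdiff(unique(agg$trait), "mass"))
  tab <- data.frame(species = species, stringsAsFactors = FALSE)
  for (tr in c("mass", traits)) {
    col <- rep(NA_real_, length(species))
    sel <- agg$trait == tr
    col[match(agg$species[sel], species)] <- agg$value[sel]
    tab[[tr]] <- col
  }
  # mass is mandatory
  tab <- tab[!is.na(tab$mass), , drop = FALSE]
  if (nrow(tab) == 0) stop("no species with qualifying body mass remain")

  # append the target row from its separate source
  target_values <- unlist(target_values)
  if (!"mass" %in% names(target_values)) {
    stop("target_values must include 'mass'")
  }
  if (any(target_values <= 0 | !is.finite(target_values))) {
    stop("target values must be positive and finite (native scale)")
  }
  trow <- as.list(rep(NA_real_, ncol(tab) - 1))
  names(trow) <- names(tab)[-1]
  for (tr in intersect(names(target_values), names(trow))) {
    trow[[tr]] <- log10(target_values[[tr]])
  }
  tab <- rbind(tab, c(list(species = normalize_label(target_species)), trow))
  rownames(tab) <- NULL

  structure(tab, class = c("trait_table", "data.frame"),
            target = normalize_label(target_species), audit = audit)
}

#' Species, mass and values available for one trait
#'
#' Returns only the species with a value for the requested trait (plus their
#' mass); rows are ordered alphabetically by species label, which is the
#' canonical ordering used throughout the package.
#'
#' @param table A `trait_table`.
#' @param trait Trait column name.
#' @return A list with `species`, `mass` and `value` vectors.
#' @export
trait_subset <- function(table, trait) {
  if (!trait %in% setdiff(names(table), c("species", "mass"))) {
    stop("unknown trait: ", trait)
  }
  keep <- !is.na(table[[trait]]) & !is.na(table$mass)
  sub <- table[keep, , drop = FALSE]
  ord <- order(sub$species)
  list(species = sub$species[ord],
       mass = sub$mass[ord],
       value = sub[[trait]][ord])
}

#' Write a trait table to CSV with a JSON audit sidecar
#'
#' @param table A `trait_table`.
#' @param path Output CSV path; the audit log is written next to it as
#'   `<path>.audit.json`.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(target = attr(table, "target"), audit = attr(table, "audit"))
  jsonlite::write_json(meta, paste0(path, ".audit.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a trait table written by [write_trait_table()]
#' @param path CSV path.
#' @return A `trait_table`.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".audit.json")
  target <- NA_character_
  audit <- list()
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    target <- meta$target
    audit <- meta$audit
  }
  structure(tab, class = c("trait_table", "data.frame"),
            target = target, audit = audit)
}

# Wrap an existing wide data frame (species, mass, traits...) as trait_table.
as_trait_table <- function(df, target) {
  stopifnot(all(c("species", "mass") %in% names(df)))
  df$species <- normalize_label(df$species)
  structure(df, class = c("trait_table", "data.frame"),
            target = normalize_label(target), audit = list())
}
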