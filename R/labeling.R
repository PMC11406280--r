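#' Validate a taxonomy table
#'
#' @param df data frame with character columns `species`, `genus`, `family`.
#' @return the validated taxonomy data frame (one row per species).
#' @export
read_taxonomy <- function(df) {
  if (is.character(df) && length(df) == 1) df <- utils::read.csv(df, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "genus", "family") %in% names(df)))
  df <- unique(df[, c("species", "genus", "family")])
  if (nrow(df) == 0) stop("taxonomy table is empty", call. = FALSE)
  if (anyDuplicated(df$species)) {
    stop("taxonomy maps a species to more than one genus/family", call. = FALSE)
  }
  gf <- unique(df[, c("genus", "family")])
  if (anyDuplicated(gf$genus)) {
    stop("taxonomy maps a genus to more than one family", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Impute community labels from neighboring observations
#'
#' Converts curated single-species occurrences into multilabel anchors: each
#' occurrence becomes one anchor whose species set is its own species plus the
#' species of every occurrence within `radius_m` (center distance, i.e.
#' overlapping square image footprints of side `radius_m`). Anchors are never
#' merged; imputation is symmetric by construction.
#'
#' @param occs curated occurrence data frame (deduplicated).
#' @param radius_m imputation radius, meters.
#' @return an `sdm_labels` object: list with `anchors` (data frame
#'   `anchor_id, x, y`), `species` (list of character vectors, one per
#'   anchor), `radius_m`, `crs`.
#' @export
neighbor_impute <- function(occs, radius_m = 256) {
  n <- nrow(occs)
  r2 <- radius_m^2
  sets <- vector("list", n)
  # block over rows to keep the distance computation vectorized yet bounded
  block <- 512L
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    dx2 <- outer(occs$x[idx], occs$x, `-`)^2 + outer(occs$y[idx], occs$y, `-`)^2
    for (k in seq_along(idx)) {
      sets[[idx[k]]] <- sort(unique(occs$species[dx2[k, ] <= r2]))
    }
  }
  structure(
    list(anchors = data.frame(anchor_id = occs$record_id,
                              x = occs$x, y = occs$y,
                              stringsAsFactors = FALSE),
         species = sets,
         radius_m = radius_m,
         crs = attr(occs, "crs")),
    class = "sdm_labels")
}

#' @export
print.sdm_labels <- function(x, ...) {
  cat(sprintf("<sdm_labels> %d anchors, %d species, mean set size %.2f\n",
              nrow(x$anchors), length(unique(unlist(x$species))),
              mean(lengths(x$species))))
  invisible(x)
}

#' Expand species label sets to genus and family ranks
#'
#' Indexes every taxon lexicographically by name (a fixed, serializable
#' ordering) and fills genus and family index sets as the taxonomy image of
#' each anchor's species set.
#'
#' @param labels an `sdm_labels` object.
#' @param taxonomy taxonomy data frame (see [read_taxonomy()]).
#' @return the labels object with added fields: `index` (list of character
#'   vectors `species`, `genus`, `family`, plus integer maps
#'   `species_genus`, `species_family`) and `species_idx`, `genus_idx`,
#'   `family_idx` (lists of integer vectors, 1-based).
#' @export
expand_ranks <- function(labels, taxonomy) {
  taxonomy <- read_taxonomy(taxonomy)
  sp_all <- sort(unique(unlist(labels$species, use.names = FALSE)))
  missing_sp <- setdiff(sp_all, taxonomy$species)
  if (length(missing_sp)) {
    stop("species missing from taxonomy: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  tax <- taxonomy[match(sp_all, taxonomy$species), ]
  gen_all <- sort(unique(tax$genus))
  fam_all <- sort(unique(tax$family))
  sp_gen <- match(tax$genus, gen_all)
  sp_fam <- match(tax$family, fam_all)
  labels$index <- list(species = sp_all, genus = gen_all, family = fam_all,
                       species_genus = sp_gen, species_family = sp_fam)
  labels$species_idx <- lapply(labels$species, function(s) match(s, sp_all))
  labels$genus_idx <- lapply(labels$species_idx, function(i) sort(unique(sp_gen[i])))
  labels$family_idx <- lapply(labels$species_idx, function(i) sort(unique(sp_fam[i])))
  labels
}

#' Serialize label sets
#'
#' Writes one CSV row per (anchor, rank, taxon) membership plus a JSON file
#' mapping taxon names to indices.
#'
#' @param labels an indexed `sdm_labels` object (after [expand_ranks()]).
#' @param csv_path,json_path output paths.
#' @export
write_labels <- function(labels, csv_path, json_path) {
  stopifnot(!is.null(labels$index))
  rows <- do.call(rbind, lapply(seq_along(labels$species_idx), function(i) {
    aid <- labels$anchors$anchor_id[i]
    rbind(
      data.frame(anchor_id = aid, rank = "species",
                 taxon_index = labels$species_idx[[i]],
                 taxon_name = labels$index$species[labels$species_idx[[i]]]),
      data.frame(anchor_id = aid, rank = "genus",
                 taxon_index = labels$genus_idx[[i]],
                 taxon_name = labels$index$genus[labels$genus_idx[[i]]]),
      data.frame(anchor_id = aid, rank = "family",
                 taxon_index = labels$family_idx[[i]],
                 taxon_name = labels$index$family[labels$family_idx[[i]]]))
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  jsonlite::write_json(labels$index, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
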