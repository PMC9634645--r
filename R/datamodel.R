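# Domain tables and their validators. All tables are plain data.frames with
# fixed column sets; readers validate invariants and report offending rows.

DYE_COLORS <- c("blue", "pink", "orange", "yellow")
ECOTYPES <- c("Ca", "Si")

plant_columns <- c("plant_id", "population_id", "ecotype", "x", "y", "role",
                   "n_inflorescences", "open_flowers", "n_flowers_sampled")
dye_columns <- c("plant_id", "flower_id", "dye_color", "particle_count")
camera_columns <- c("population_id", "ecotype", "date", "duration_h",
                    "n_flowers_filmed", "n_flowers_visited", "n_moths",
                    "visits_per_h", "moths_per_h")
germination_columns <- c("population_id", "ecotype", "n_seeds_plated",
                         "n_germinated", "n_chlorotic",
                         "n_partially_chlorotic")

fail_rows <- function(what, rows) {
  stop(what, " (row", if (length(rows) > 1) "s", " ",
       paste(rows, collapse = ", "), ")", call. = FALSE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column", if (length(missing) > 1) "s", " in ",
         what, " table: ", paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Parse a semicolon-separated list of per-inflorescence flower counts
#'
#' Plant tables store the open-flower counts of up to five inflorescences as
#' a single `"a;b;c"` field; this expands it to a list of integer vectors.
#'
#' @param x character vector of semicolon-joined counts (may be `""`).
#' @return list of integer vectors (length-0 for empty fields).
#' @export
parse_flower_counts <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(integer(0))
    as.integer(strsplit(trimws(s), ";", fixed = TRUE)[[1]])
  })
}

#' Validate a plant table
#'
#' Checks the invariants of the mapped-individual table: finite planar
#' coordinates (meters), known ecotype and role labels, non-negative counts,
#' and at least one sampled flower for recipients.
#'
#' @param plants data.frame with columns `plant_id`, `population_id`,
#'   `ecotype` (`"Ca"`/`"Si"`), `x`, `y` (meters, planar), `role`
#'   (`"source"`/`"recipient"`), `n_inflorescences`, `open_flowers`
#'   (semicolon-joined counts for up to five inflorescences),
#'   `n_flowers_sampled`.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_plants <- function(plants) {
  check_columns(plants, plant_columns, "plant")
  bad <- which(!is.finite(plants$x) | !is.finite(plants$y))
  if (length(bad)) fail_rows("non-finite coordinate", bad)
  bad <- which(!plants$ecotype %in% ECOTYPES)
  if (length(bad)) fail_rows("unknown ecotype label", bad)
  bad <- which(!plants$role %in% c("source", "recipient"))
  if (length(bad)) fail_rows("unknown role", bad)
  bad <- which(plants$n_inflorescences < 0 | plants$n_flowers_sampled < 0)
  if (length(bad)) fail_rows("negative count", bad)
  bad <- which(plants$role == "recipient" & plants$n_flowers_sampled < 1)
  if (length(bad)) fail_rows("recipient with no sampled flowers", bad)
  bad <- which(duplicated(plants$plant_id))
  if (length(bad)) fail_rows("duplicated plant_id", bad)
  counts <- parse_flower_counts(plants$open_flowers)
  bad <- which(vapply(counts, function(v) any(v < 0) | length(v) > 5, TRUE))
  if (length(bad)) fail_rows("invalid open-flower counts", bad)
  plants
}

#' Validate a dye-observation table
#'
#' One row per flower x dye color with the particle count summed over the
#' three stigmas of the flower. `(plant_id, flower_id, dye_color)` must be
#' unique and counts non-negative.
#'
#' @param dye data.frame with columns `plant_id`, `flower_id`, `dye_color`,
#'   `particle_count`.
#' @return the validated data.frame.
#' @export
validate_dye <- function(dye) {
  check_columns(dye, dye_columns, "dye")
  if (nrow(dye) == 0) return(dye)
  bad <- which(dye$particle_count < 0)
  if (length(bad)) fail_rows("negative particle_count", bad)
  bad <- which(!dye$dye_color %in% DYE_COLORS)
  if (length(bad)) fail_rows("unknown dye color", bad)
  key <- paste(dye$plant_id, dye$flower_id, dye$dye_color)
  bad <- which(duplicated(key))
  if (length(bad)) fail_rows("duplicated (plant, flower, color) observation", bad)
  dye
}

#' Validate a community abundance table
#'
#' Rows are population-year samples, taxon columns hold non-negative integer
#' abundances; `population_id`, `ecotype` and `year` are row metadata.
#'
#' @param comm data.frame with `population_id`, `ecotype`, `year` plus one
#'   numeric column per taxon group.
#' @return the validated data.frame.
#' @export
validate_community <- function(comm) {
  check_columns(comm, c("population_id", "ecotype", "year"), "community")
  taxa <- community_taxa(comm)
  if (length(taxa) == 0) stop("community table has no taxon columns", call. = FALSE)
  m <- as.matrix(comm[, taxa, drop = FALSE])
  bad <- which(apply(m < 0 | m != round(m), 1, any))
  if (length(bad)) fail_rows("taxon abundance not a non-negative integer", bad)
  key <- paste(comm$population_id, comm$year)
  bad <- which(duplicated(key))
  if (length(bad)) fail_rows("duplicated population-year row", bad)
  comm
}

community_taxa <- function(comm) {
  setdiff(names(comm), c("population_id", "ecotype", "year", "valley"))
}

#' Taxon column names of a community table
#'
#' @param comm community table.
#' @return character vector of taxon column names (everything that is not
#'   row metadata).
#' @export
community_taxa_names <- function(comm) community_taxa(comm)

#' Validate a camera-observation table
#'
#' One row per camera recording; the per-hour rates must agree with the raw
#' counts divided by the recording duration (within rounding of the printed
#' two-decimal rates).
#'
#' @param cam data.frame with columns `population_id`, `ecotype`, `date`,
#'   `duration_h`, `n_flowers_filmed`, `n_flowers_visited`, `n_moths`,
#'   `visits_per_h`, `moths_per_h`.
#' @return the validated data.frame.
#' @export
validate_camera <- function(cam) {
  check_columns(cam, camera_columns, "camera")
  bad <- which(cam$duration_h <= 0)
  if (length(bad)) fail_rows("non-positive recording duration", bad)
  bad <- which(abs(cam$visits_per_h - cam$n_flowers_visited / cam$duration_h) > 0.05 |
               abs(cam$moths_per_h - cam$n_moths / cam$duration_h) > 0.05)
  if (length(bad)) fail_rows("rate inconsistent with count/duration", bad)
  cam
}

#' Validate a germination table
#'
#' @param germ data.frame with columns `population_id`, `ecotype`,
#'   `n_seeds_plated`, `n_germinated`, `n_chlorotic`, `n_partially_chlorotic`.
#' @return the validated data.frame.
#' @export
validate_germination <- function(germ) {
  check_columns(germ, germination_columns, "germination")
  bad <- which(germ$n_germinated > germ$n_seeds_plated)
  if (length(bad)) fail_rows("more germinated than plated", bad)
  bad <- which(germ$n_chlorotic + germ$n_partially_chlorotic > germ$n_germinated)
  if (length(bad)) fail_rows("more chlorotic than germinated", bad)
  bad <- which(as.matrix(germ[, germination_columns[-(1:2)]]) < 0)
  if (length(bad)) fail_rows("negative count", unique((bad - 1) %% nrow(germ) + 1))
  germ
}

#' Read and validate the analysis input tables
#'
#' Thin CSV readers (UTF-8, comma separator, mandatory header, `.` decimal
#' mark) that validate every invariant on load. Each reader has a matching
#' `write_table()` such that a written table reads back identically.
#'
#' @param path CSV file path.
#' @return validated data.frame of the corresponding table type.
#' @name readers
NULL

read_checked <- function(path, validator) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validator(read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"))
}

#' @rdname readers
#' @export
read_plant_table <- function(path) {
  df <- read_checked(path, validate_plants)
  df$open_flowers <- as.character(df$open_flowers)
  df$open_flowers[is.na(df$open_flowers)] <- ""
  df
}

#' @rdname readers
#' @export
read_dye_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 colClasses = c(plant_id = "character", flower_id = "character"))
  validate_dye(df)
}

#' @rdname readers
#' @export
read_community_table <- function(path) read_checked(path, validate_community)

#' @rdname readers
#' @export
read_camera_table <- function(path) read_checked(path, validate_camera)

#' @rdname readers
#' @export
read_germination_table <- function(path) read_checked(path, validate_germination)

#' Write a table as CSV
#'
#' @param df any of the validated tables.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Euclidean distance between two mapped plants
#'
#' Coordinates must be planar projected meters; see [latlon_to_planar()] for
#' converting geographic coordinates beforehand.
#'
#' @param a,b one-row data.frames (or lists) with numeric `x` and `y`.
#' @return distance in meters.
#' @export
pairwise_distance <- function(a, b) {
  ax <- as.numeric(a[["x"]]); ay <- as.numeric(a[["y"]])
  bx <- as.numeric(b[["x"]]); by <- as.numeric(b[["y"]])
  if (!all(is.finite(c(ax, ay, bx, by)))) stop("non-finite coordinate")
  sqrt((ax - bx)^2 + (ay - by)^2)
}

#' Full pairwise distance matrix for a plant table
#'
#' @param plants validated plant table.
#' @return symmetric matrix of distances in meters, dimnames = plant ids.
#' @export
distance_matrix <- function(plants) {
  if (any(!is.finite(plants$x) | !is.finite(plants$y)))
    stop("non-finite coordinate")
  d <- as.matrix(dist(cbind(plants$x, plants$y)))
  dimnames(d) <- list(plants$plant_id, plants$plant_id)
  d
}

#' Convert geographic coordinates to local planar meters
#'
#' Equirectangular projection around a local origin; adequate over the few
#' kilometers spanned by a parapatric population pair. Analysis functions
#' accept planar meters only, so this helper is applied before building any
#' table.
#'
#' @param lat,lon numeric degrees.
#' @param origin length-2 numeric `c(lat0, lon0)`; defaults to the centroid.
#' @return data.frame with `x`, `y` in meters.
#' @export
latlon_to_planar <- function(lat, lon, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(lat), mean(lon))
  R <- 6371008.8
  data.frame(
    x = R * cos(origin[1] * pi / 180) * (lon - origin[2]) * pi / 180,
    y = R * (lat - origin[1]) * pi / 180
  )
}

#' Estimate the total flower number of a recipient plant
#'
#' Total flowers are estimated as the inflorescence number times the mean
#' open-flower count over the (up to five) counted inflorescences, the usual
#' field proxy for floral display size.
#'
#' @param n_inflorescences count of inflorescences (>= 1).
#' @param open_flower_counts integer vector of open-flower counts, length
#'   1-5.
#' @return estimated total flower number (real).
#' @export
estimate_total_flowers <- function(n_inflorescences, open_flower_counts) {
  if (length(open_flower_counts) == 0)
    stop("no open-flower counts recorded; cannot estimate total flowers")
  if (n_inflorescences < 1) stop("n_inflorescences must be >= 1")
  n_inflorescences * mean(open_flower_counts)
}

#' Derive the per-recipient dye-transfer table
#'
#' Builds one record per recipient individual x dye color: the distance `r`
#' from the recipient to the centroid of the color's source group, the mean
#' dye count per flower, the summed count, the number of flowers carrying at
#' least one particle, and the transfer classification. Sampled flowers with
#' no observation row for a color are zero-count by protocol (every collected
#' flower was scored).
#'
#' @param plants validated plant table; each source population must contain
#'   at least one `role == "source"` plant unless `source_map` carries
#'   explicit `x`, `y` columns.
#' @param dye_obs validated dye-observation table.
#' @param source_map data.frame mapping `dye_color` to `source_population`
#'   (one row per color; optional `x`, `y` override the source-group
#'   centroid).
#' @return data.frame with columns `recipient_id`, `recipient_population`,
#'   `recipient_ecotype`, `source_population`, `source_ecotype`, `dye_color`,
#'   `r`, `mean_count_per_flower`, `sum_count`, `n_flowers_positive`,
#'   `n_flowers_sampled`, `total_flowers_est`, `transfer_class`, `direction`.
#' @export
build_transfer_table <- function(plants, dye_obs, source_map) {
  plants <- validate_plants(plants)
  dye_obs <- validate_dye(dye_obs)
  check_columns(source_map, c("dye_color", "source_population"), "source map")
  if (anyDuplicated(source_map$dye_color))
    stop("each dye color must map to exactly one source population")
  unmapped <- setdiff(unique(dye_obs$dye_color), source_map$dye_color)
  if (length(unmapped))
    stop("dye color with no source mapping: ", paste(unmapped, collapse = ", "))
  unknown_plants <- setdiff(unique(dye_obs$plant_id), plants$plant_id)
  if (length(unknown_plants))
    stop("dye observations for unmapped plants: ",
         paste(unknown_plants, collapse = ", "))

  eco_of <- function(pop) {
    e <- unique(plants$ecotype[plants$population_id == pop])
    if (length(e) != 1) stop("population ", pop, " lacks a unique ecotype label")
    e
  }
  src_xy <- function(i) {
    if (all(c("x", "y") %in% names(source_map)) &&
        is.finite(source_map$x[i]) && is.finite(source_map$y[i]))
      return(c(source_map$x[i], source_map$y[i]))
    s <- plants[plants$role == "source" &
                plants$population_id == source_map$source_population[i], ]
    if (nrow(s) == 0)
      stop("no source plants in population ", source_map$source_population[i])
    c(mean(s$x), mean(s$y))
  }

  rec <- plants[plants$role == "recipient", ]
  flower_lists <- parse_flower_counts(rec$open_flowers)
  out <- vector("list", nrow(source_map))
  for (i in seq_len(nrow(source_map))) {
    col <- source_map$dye_color[i]
    spop <- source_map$source_population[i]
    seco <- eco_of(spop)
    xy <- src_xy(i)
    obs <- dye_obs[dye_obs$dye_color == col & dye_obs$particle_count > 0, ]
    sums <- tapply(obs$particle_count, obs$plant_id, sum)
    npos <- tapply(obs$particle_count, obs$plant_id, function(v) sum(v >= 1))
    sum_count <- as.numeric(sums[rec$plant_id]); sum_count[is.na(sum_count)] <- 0
    n_pos <- as.numeric(npos[rec$plant_id]); n_pos[is.na(n_pos)] <- 0
    reco <- rec$ecotype
    cls <- ifelse(rec$population_id == spop, "intrapopulation",
                  ifelse(reco == seco, "intra_ecotypic", "inter_ecotypic"))
    tfe <- vapply(seq_len(nrow(rec)), function(j) {
      fl <- flower_lists[[j]]
      if (length(fl) == 0) NA_real_
      else estimate_total_flowers(rec$n_inflorescences[j], fl)
    }, numeric(1))
    out[[i]] <- data.frame(
      recipient_id = rec$plant_id,
      recipient_population = rec$population_id,
      recipient_ecotype = reco,
      source_population = spop,
      source_ecotype = seco,
      dye_color = col,
      r = sqrt((rec$x - xy[1])^2 + (rec$y - xy[2])^2),
      mean_count_per_flower = sum_count / rec$n_flowers_sampled,
      sum_count = sum_count,
      n_flowers_positive = n_pos,
      n_flowers_sampled = rec$n_flowers_sampled,
      total_flowers_est = tfe,
      transfer_class = cls,
      direction = paste0(seco, "To", reco),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dye-deposition summary per source x recipient population pair
#'
#' For each (source population, recipient population) pair: the percentage of
#' recipient individuals with any dye of that source's color (`sum_count >=
#' 1`), and the mean and standard error, over recipient individuals, of the
#' per-individual percentage of sampled flowers carrying at least one
#' particle.
#'
#' @param transfers transfer table from [build_transfer_table()].
#' @return data.frame with `source_population`, `recipient_population`,
#'   `n_recipients`, `pct_individuals_with_dye`, `mean_pct_flowers_with_dye`,
#'   `se_pct_flowers_with_dye`.
#' @export
transfer_summary <- function(transfers) {
  key <- interaction(transfers$source_population,
                     transfers$recipient_population, drop = TRUE)
  rows <- lapply(split(transfers, key), function(g) {
    pct_fl <- 100 * g$n_flowers_positive / g$n_flowers_sampled
    data.frame(
      source_population = g$source_population[1],
      recipient_population = g$recipient_population[1],
      n_recipients = nrow(g),
      pct_individuals_with_dye = 100 * mean(g$sum_count >= 1),
      mean_pct_flowers_with_dye = mean(pct_fl),
      se_pct_flowers_with_dye = if (nrow(g) > 1) sd(pct_fl) / sqrt(nrow(g)) else 0,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$source_population, res$recipient_population), ]
}
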