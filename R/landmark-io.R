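#' Landmark dataset container
#'
#' A `landmark_dataset` bundles raw 2-D landmark configurations (one per
#' digitized specimen) with their specimen-level metadata. Coordinates follow
#' the mathematical convention: x increases rightward, y increases upward.
#' Data digitized in image pixel coordinates (y down) must be flipped by the
#' data producer before import; superimposition does not allow reflections,
#' so a mixed-convention dataset cannot be rescued downstream.
#'
#' @param coords numeric array of dimension `k x 2 x n` (landmarks x (x, y) x
#'   specimens), or a list of `n` matrices each `k x 2`. Landmark order must
#'   be identical across specimens.
#' @param meta data frame with one row per specimen. Recognised columns:
#'   `specimen`, `species`, `genus`, `site`, `date`, `observer`, `replicate`.
#'   Missing columns are created empty (`""`).
#' @return An object of class `landmark_dataset` with elements `coords`
#'   (k x 2 x n array), `meta` (data frame) and `k`.
#' @examples
#' tri <- array(c(0, 1, 0, 0, 0, 1), dim = c(3, 2, 1))
#' d <- landmark_dataset(tri, data.frame(specimen = "s1", species = "sp"))
#' d$k
#' @export
landmark_dataset <- function(coords, meta = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    k <- nrow(coords[[1]])
    coords <- array(unlist(lapply(coords, function(m) {
      m <- as.matrix(m)
      if (!identical(dim(m), c(k, 2L)) && !identical(dim(m), as.integer(c(k, 2))))
        stop("all configurations must be k x 2 with identical k")
      m
    })), dim = c(k, 2, length(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 2L)
    stop("'coords' must be a k x 2 x n array")
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  if (k < 3L) stop("at least 3 landmarks are required (k >= 3)")
  if (!all(is.finite(coords))) stop("all landmark coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y"), NULL)

  meta_cols <- c("specimen", "species", "genus", "site", "date",
                 "observer", "replicate")
  if (is.null(meta)) meta <- data.frame(specimen = paste0("spec", seq_len(n)))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop("'meta' must have one row per specimen")
  for (cc in meta_cols) {
    if (is.null(meta[[cc]])) meta[[cc]] <- ""
    meta[[cc]] <- as.character(meta[[cc]])
    meta[[cc]][is.na(meta[[cc]])] <- ""
  }
  meta <- meta[meta_cols]
  key <- paste(meta$specimen, meta$observer, meta$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (specimen, observer, replicate) keys: ",
         paste(unique(meta$specimen[duplicated(key)]), collapse = ", "))
  structure(list(coords = coords, meta = meta, k = k),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  n <- dim(x$coords)[3]
  cat("Landmark dataset: ", n, " configurations x ", x$k, " landmarks (2-D)\n",
      sep = "")
  sp <- unique(x$meta$species[nzchar(x$meta$species)])
  if (length(sp))
    cat("Species (", length(sp), "): ",
        paste(utils::head(sp, 8), collapse = ", "),
        if (length(sp) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of specimens in a landmark dataset
#' @param dataset a `landmark_dataset`
#' @return integer count of configurations
#' @export
n_specimens <- function(dataset) dim(dataset$coords)[3]

#' Subset a landmark dataset by specimen index
#' @param dataset a `landmark_dataset`
#' @param idx integer or logical index over specimens
#' @return a `landmark_dataset` with the selected configurations
#' @export
subset_specimens <- function(dataset, idx) {
  landmark_dataset(dataset$coords[, , idx, drop = FALSE],
                   dataset$meta[idx, , drop = FALSE])
}

#' Read landmark configurations from TPS or CSV
#'
#' The TPS dialect is the classic morphometrics exchange format: each record
#' is `LM=<k>`, then `k` lines of `x y`, then `ID=<id>` and optionally
#' `IMAGE=<name>`; records are separated by blank lines (a new `LM=` line also
#' starts a record). CSV is the canonical dialect here because it carries the
#' full metadata (species, genus, site, date, observer, replicate); columns
#' are the metadata columns followed by `x1,y1,...,xk,yk`.
#'
#' @param path path to an existing file
#' @param format `"csv"` or `"tps"`; default guessed from the file extension
#' @return a [landmark_dataset()]
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "tps")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tps") read_tps(path) else read_landmark_csv(path)
}

read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  rec_no <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    m <- regmatches(lines[i], regexec("^\\s*LM\\s*=\\s*([0-9]+)\\s*$", lines[i],
                                      ignore.case = TRUE))[[1]]
    if (length(m) < 2)
      stop("TPS parse error at line ", i, ": expected 'LM=<k>', got '",
           lines[i], "'")
    rec_no <- rec_no + 1L
    k <- as.integer(m[2])
    xy <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      i <- i + 1L
      if (i > length(lines))
        stop("TPS parse error: record ", rec_no, " truncated (expected ", k,
             " coordinate lines)")
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(v) != 2 || anyNA(v))
        stop("TPS parse error at line ", i, ": non-numeric coordinate in '",
             lines[i], "'")
      xy[j, ] <- v
    }
    id <- paste0("spec", rec_no); image <- ""
    while (i + 1L <= length(lines) &&
           grepl("^\\s*[A-Za-z]+\\s*=", lines[i + 1L])) {
      i <- i + 1L
      kv <- regmatches(lines[i], regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$",
                                         lines[i]))[[1]]
      if (toupper(kv[2]) == "ID") id <- trimws(kv[3])
      if (toupper(kv[2]) == "IMAGE") image <- trimws(kv[3])
    }
    recs[[rec_no]] <- list(k = k, xy = xy, id = id, image = image)
    i <- i + 1L
  }
  if (!length(recs)) stop("no TPS records found in ", path)
  ks <- vapply(recs, function(r) r$k, integer(1))
  if (length(unique(ks)) != 1L) {
    bad <- which(ks != ks[1])[1]
    stop("inconsistent landmark counts: record ", bad, " has LM=", ks[bad],
         " but record 1 has LM=", ks[1])
  }
  landmark_dataset(lapply(recs, function(r) r$xy),
                   data.frame(specimen = vapply(recs, function(r) r$id,
                                                character(1))))
}

read_landmark_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  coord_cols <- grep("^[xy][0-9]+$", names(df), value = TRUE)
  kx <- sum(grepl("^x", coord_cols)); ky <- sum(grepl("^y", coord_cols))
  if (kx < 3 || kx != ky)
    stop("CSV must contain matched coordinate columns x1,y1,...,xk,yk (k >= 3)")
  k <- kx
  ord <- as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k)))
  if (!all(ord %in% names(df)))
    stop("missing coordinate columns: ",
         paste(setdiff(ord, names(df)), collapse = ", "))
  num <- suppressWarnings(vapply(df[ord], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop("non-numeric coordinate at data line ", bad + 1L, " of ", path)
  }
  n <- nrow(df)
  coords <- array(0, dim = c(k, 2, n))
  for (i in seq_len(n)) coords[, , i] <- matrix(num[i, ], k, 2, byrow = TRUE)
  landmark_dataset(coords, df[setdiff(names(df), ord)])
}

#' Write landmark configurations to TPS or CSV
#'
#' CSV output preserves coordinates to full double precision, so
#' `read_landmarks(write_landmarks(...))` is the identity on valid datasets.
#' TPS output carries the specimen id only (the dialect has no metadata
#' fields beyond ID/IMAGE).
#'
#' @param dataset a [landmark_dataset()]
#' @param path output file path
#' @param format `"csv"` or `"tps"`
#' @return invisibly, `path`
#' @export
write_landmarks <- function(dataset, path, format = c("auto", "csv", "tps")) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  n <- n_specimens(dataset); k <- dataset$k
  if (format == "tps") {
    out <- character(0)
    for (i in seq_len(n)) {
      xy <- dataset$coords[, , i]
      out <- c(out, paste0("LM=", k),
               sprintf("%.17g %.17g", xy[, 1], xy[, 2]),
               paste0("ID=", dataset$meta$specimen[i]), "")
    }
    writeLines(out, path)
  } else {
    coord <- matrix(NA_character_, n, 2L * k)
    for (i in seq_len(n))
      coord[i, ] <- sprintf("%.17g", as.vector(t(dataset$coords[, , i])))
    coord <- as.data.frame(coord, stringsAsFactors = FALSE)
    names(coord) <- as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k)))
    utils::write.csv(cbind(dataset$meta, coord), path, row.names = FALSE,
                     quote = TRUE)
  }
  invisible(path)
}

#' Design-level validation of a landmark dataset
#'
#' Reports per-species specimen and sampling-site counts, flags species
#' sampled from fewer than `min_sites_per_species` distinct sites (the study
#' design requires specimens of each species from at least three sites, so
#' that within-species shape variation is not confounded with a single
#' location), and lists exactly coincident landmark pairs within any
#' configuration. Purely diagnostic: the dataset is never modified.
#'
#' @param dataset a [landmark_dataset()]
#' @param min_sites_per_species minimum number of distinct sites per species
#' @return a `validation_report` list with elements `species_table`
#'   (species, n_specimens, n_sites, ok), `flagged_species`,
#'   `duplicate_landmarks` (specimen, landmark_i, landmark_j; 1-based), `ok`.
#' @export
validate_dataset <- function(dataset, min_sites_per_species = 3) {
  stopifnot(inherits(dataset, "landmark_dataset"), n_specimens(dataset) > 0)
  meta <- dataset$meta
  sp <- sort(unique(meta$species))
  tab <- data.frame(
    species = sp,
    n_specimens = vapply(sp, function(s) sum(meta$species == s), integer(1)),
    n_sites = vapply(sp, function(s)
      length(unique(meta$site[meta$species == s & nzchar(meta$site)])),
      integer(1)),
    stringsAsFactors = FALSE)
  tab$ok <- tab$n_sites >= min_sites_per_species
  dup <- list()
  for (i in seq_len(n_specimens(dataset))) {
    xy <- dataset$coords[, , i]
    d <- as.matrix(stats::dist(xy))
    ties <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
    if (nrow(ties))
      dup[[length(dup) + 1L]] <- data.frame(
        specimen = meta$specimen[i],
        landmark_i = ties[, 1], landmark_j = ties[, 2])
  }
  dup <- if (length(dup)) do.call(rbind, dup) else
    data.frame(specimen = character(0), landmark_i = integer(0),
               landmark_j = integer(0))
  structure(list(species_table = tab,
                 flagged_species = tab$species[!tab$ok],
                 duplicate_landmarks = dup,
                 min_sites_per_species = min_sites_per_species,
                 ok = all(tab$ok) && nrow(dup) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Landmark dataset validation (min sites/species = ",
      x$min_sites_per_species, ")\n", sep = "")
  print(x$species_table, row.names = FALSE)
  if (length(x$flagged_species))
    cat("Species below site threshold: ",
        paste(x$flagged_species, collapse = ", "), "\n", sep = "")
  if (nrow(x$duplicate_landmarks))
    cat("Configurations with coincident landmarks: ",
        nrow(x$duplicate_landmarks), " tie(s)\n", sep = "")
  if (x$ok) cat("All checks passed.\n")
  invisible(x)
}
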