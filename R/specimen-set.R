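#' Construct a specimen set of raw landmark configurations
#'
#' A `specimen_set` holds one L x 3 landmark configuration per flower in raw
#' (scanner) units, together with specimen and species identifiers, landmark
#' labels and an optional species-to-pollination-syndrome map.  It is the
#' entry container for the whole pipeline; coordinates are unitless because
#' all shape statistics operate after Procrustes scaling.
#'
#' @param coords L x 3 x N numeric array of landmark coordinates
#'   (landmarks, xyz, specimens).
#' @param specimen_id character vector of length N, unique.
#' @param species character vector of length N.
#' @param landmark_labels character vector of length L; defaults to
#'   `lm1..lmL`.
#' @param syndrome_map optional data.frame with columns `species`,
#'   `syndrome` (one of `generalist`, `bird`, `lpf`, `wind`, `unknown`) and
#'   optionally `status` (`observed` or `predicted`).
#' @return an object of class `specimen_set`.
#' @export
specimen_set <- function(coords, specimen_id, species, landmark_labels = NULL,
                         syndrome_map = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("`coords` must be an L x 3 x N array")
  L <- dim(coords)[1]
  N <- dim(coords)[3]
  if (length(specimen_id) != N || length(species) != N)
    stop("specimen_id and species must have one entry per specimen")
  if (anyDuplicated(specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", "))
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in specimen(s): ",
         paste(specimen_id[apply(coords, 3, function(m) !all(is.finite(m)))],
               collapse = ", "))
  if (is.null(landmark_labels)) landmark_labels <- paste0("lm", seq_len(L))
  if (length(landmark_labels) != L)
    stop("landmark_labels must have length L = ", L)
  syndrome_map <- validate_syndrome_map(syndrome_map, unique(species))
  dimnames(coords) <- list(landmark_labels, c("x", "y", "z"), specimen_id)
  structure(list(coords = coords,
                 specimen_id = as.character(specimen_id),
                 species = as.character(species),
                 landmark_labels = as.character(landmark_labels),
                 syndrome_map = syndrome_map),
            class = "specimen_set")
}

validate_syndrome_map <- function(syndrome_map, species_seen) {
  syndromes <- c("generalist", "bird", "lpf", "wind", "unknown")
  if (is.null(syndrome_map)) {
    syndrome_map <- data.frame(species = species_seen,
                               syndrome = "unknown",
                               status = "predicted",
                               stringsAsFactors = FALSE)
    return(syndrome_map)
  }
  stopifnot(is.data.frame(syndrome_map),
            all(c("species", "syndrome") %in% names(syndrome_map)))
  bad <- setdiff(syndrome_map$syndrome, syndromes)
  if (length(bad))
    stop("unknown syndrome label(s): ", paste(bad, collapse = ", "))
  if (is.null(syndrome_map$status)) syndrome_map$status <- "observed"
  missing_sp <- setdiff(species_seen, syndrome_map$species)
  if (length(missing_sp))
    syndrome_map <- rbind(syndrome_map,
                          data.frame(species = missing_sp, syndrome = "unknown",
                                     status = "predicted"))
  syndrome_map
}

#' @export
print.specimen_set <- function(x, ...) {
  cat("specimen_set:", dim(x$coords)[3], "specimens,",
      length(unique(x$species)), "species,",
      dim(x$coords)[1], "landmarks\n")
  invisible(x)
}

#' Number of landmarks / specimens in a specimen set
#' @param x a `specimen_set`
#' @return integer
#' @export
n_landmarks <- function(x) dim(x$coords)[1]

#' @rdname n_landmarks
#' @export
n_specimens <- function(x) dim(x$coords)[3]

#' Read a landmark coordinate table
#'
#' Two dialects are supported.  `csv`: long format with columns
#' `specimen_id, species, landmark, x, y, z`, 33 (or L) rows per specimen.
#' `tps`: blocks of the form `LM3=<L>` followed by L coordinate lines and an
#' `ID=<specimen>` key (an optional `SPECIES=` comment line is honoured).
#' Landmark indices in files are 1-based.
#'
#' @param path file path.
#' @param format `"csv"` or `"tps"`.
#' @param syndrome_map optional syndrome metadata table (see
#'   [specimen_set()]).
#' @return a [specimen_set()].
#' @export
read_landmark_table <- function(path, format = c("csv", "tps"),
                                syndrome_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_landmark_csv(path, syndrome_map)
  else read_landmark_tps(path, syndrome_map)
}

read_landmark_csv <- function(path, syndrome_map) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "landmark", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  for (v in c("x", "y", "z")) {
    if (!is.numeric(df[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[v]]))))[1]
      stop("non-numeric coordinate in column '", v, "' at data line ", bad)
    }
  }
  ids <- unique(df$specimen_id)
  counts <- table(df$specimen_id)
  L <- as.integer(counts[[1]])
  if (any(counts != L))
    stop("row-count mismatch: specimen(s) ",
         paste(names(counts)[counts != L], collapse = ", "),
         " do not have ", L, " landmarks")
  first <- df[df$specimen_id == ids[1], ]
  labels <- as.character(first$landmark)
  coords <- array(NA_real_, c(L, 3, length(ids)))
  species <- character(length(ids))
  for (i in seq_along(ids)) {
    blk <- df[df$specimen_id == ids[i], ]
    ord <- match(labels, as.character(blk$landmark))
    if (anyNA(ord))
      stop("specimen ", ids[i], " is missing landmark(s): ",
           paste(setdiff(labels, blk$landmark), collapse = ", "))
    blk <- blk[ord, ]
    coords[, , i] <- as.matrix(blk[, c("x", "y", "z")])
    species[i] <- blk$species[1]
  }
  specimen_set(coords, ids, species, labels, syndrome_map)
}

read_landmark_tps <- function(path, syndrome_map) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3=", lines)
  if (!length(starts)) stop("no LM3= records found in TPS file")
  cfgs <- list(); ids <- character(); species <- character()
  for (b in seq_along(starts)) {
    i <- starts[b]
    L <- as.integer(sub("^LM3=", "", lines[i]))
    coord_lines <- lines[(i + 1):(i + L)]
    mat <- t(vapply(seq_along(coord_lines), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(coord_lines[j], "[ \t]+")[[1]]))
      if (length(v) != 3 || anyNA(v))
        stop("parse error at line ", i + j, ": expected 3 numeric coordinates")
      v
    }, numeric(3)))
    j <- i + L + 1
    id <- NA_character_; sp <- NA_character_
    while (j <= length(lines) && !grepl("^LM3=", lines[j])) {
      if (grepl("^ID=", lines[j])) id <- sub("^ID=", "", lines[j])
      if (grepl("^SPECIES=", lines[j])) sp <- sub("^SPECIES=", "", lines[j])
      j <- j + 1
    }
    if (is.na(id)) id <- paste0("specimen", b)
    if (is.na(sp)) sp <- id
    cfgs[[b]] <- mat; ids[b] <- id; species[b] <- sp
  }
  Ls <- vapply(cfgs, nrow, integer(1))
  if (length(unique(Ls)) != 1)
    stop("row-count mismatch: specimen ", ids[which(Ls != Ls[1])[1]],
         " has ", Ls[which(Ls != Ls[1])[1]], " landmarks, expected ", Ls[1])
  coords <- array(unlist(cfgs), c(Ls[1], 3, length(cfgs)))
  specimen_set(coords, ids, species, NULL, syndrome_map)
}

#' Write a specimen set as a long-format CSV
#'
#' Inverse of [read_landmark_table()] with `format = "csv"`; round-trips
#' coordinates at full double precision.
#'
#' @param x a `specimen_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(x, path) {
  L <- n_landmarks(x); N <- n_specimens(x)
  df <- data.frame(
    specimen_id = rep(x$specimen_id, each = L),
    species = rep(x$species, each = L),
    landmark = rep(x$landmark_labels, N),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ]))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a single configuration in TPS (LM3) format
#' @param config L x 3 matrix.
#' @param path output path.
#' @param id record id to write after the coordinates.
#' @return `path`, invisibly.
#' @export
write_tps <- function(config, path, id = "consensus") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LM3=%d", nrow(config)), con)
  writeLines(apply(config, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(sprintf("ID=%s", id), con)
  invisible(path)
}
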