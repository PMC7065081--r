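#' Landmark-partition hypothesis
#'
#' A named assignment of each of L landmarks to one of K >= 2 modules.  The
#' canonical hypotheses for a flower are `attraction_reproduction` (fertile
#' vs sterile organs, K = 2), `developmental` (one module per organ class:
#' sepals, petals, stamens, carpels; K = 4), and two functional partitions
#' (pollen deposition / receipt / rest, and reward-access restriction /
#' gynoecium / rest; K = 3 each).
#'
#' @param name hypothesis name.
#' @param assignment integer vector of length L with module ids; gaps in the
#'   id sequence are relabelled to 1..K with a warning.
#' @return an object of class `partition_hypothesis` with elements `name`,
#'   `assignment`, `K`.
#' @export
partition_hypothesis <- function(name, assignment) {
  assignment <- as.integer(assignment)
  if (anyNA(assignment)) stop("NA module id in partition '", name, "'")
  ids <- sort(unique(assignment))
  if (length(ids) < 2) stop("partition '", name, "' has K < 2 modules")
  if (!identical(ids, seq_along(ids))) {
    warning("module ids in partition '", name,
            "' are not 1..K; relabelling to consecutive ids")
    assignment <- match(assignment, ids)
  }
  structure(list(name = name, assignment = assignment,
                 K = length(ids)), class = "partition_hypothesis")
}

#' @export
print.partition_hypothesis <- function(x, ...) {
  cat("partition_hypothesis '", x$name, "': L = ", length(x$assignment),
      ", K = ", x$K, " (sizes ",
      paste(tabulate(x$assignment), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Read a module-map file
#'
#' The file is a CSV with a `landmark` column followed by one column per
#' modularity hypothesis; each cell gives the module id of that landmark
#' under that hypothesis.
#'
#' @param path CSV path.
#' @param landmark_labels optional character vector; when given, the file's
#'   landmark labels must match it (order-free).
#' @return named list of [partition_hypothesis()] objects.
#' @export
read_module_map <- function(path, landmark_labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"landmark" %in% names(df)) stop("module map needs a 'landmark' column")
  hyp_cols <- setdiff(names(df), "landmark")
  if (!length(hyp_cols)) stop("module map has no hypothesis columns")
  if (!is.null(landmark_labels)) {
    unknown <- setdiff(df$landmark, landmark_labels)
    if (length(unknown))
      stop("unknown landmark label(s) in module map: ",
           paste(unknown, collapse = ", "))
    if (length(setdiff(landmark_labels, df$landmark)))
      stop("module map is missing landmark(s): ",
           paste(setdiff(landmark_labels, df$landmark), collapse = ", "))
    df <- df[match(landmark_labels, df$landmark), ]
  }
  out <- lapply(hyp_cols, function(h) partition_hypothesis(h, df[[h]]))
  names(out) <- hyp_cols
  out
}

#' Write a module map
#' @param partitions named list of `partition_hypothesis` objects sharing L.
#' @param landmark_labels labels for the landmark column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_module_map <- function(partitions, landmark_labels, path) {
  df <- data.frame(landmark = landmark_labels)
  for (p in partitions) df[[p$name]] <- p$assignment
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
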