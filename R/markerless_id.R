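# Open-set markerless identification over a pluggable embedding. The encoder
# (a coat-pattern CNN upstream) is a black box here; this module owns the
# anchor dictionary: one centroid ("center of mass") per animal in the latent
# space, nearest-anchor assignment with threshold rejection, and incremental
# enrollment without retraining.

#' Build an anchor dictionary from labelled encodings
#'
#' Each animal's anchor is the coordinate-wise mean of its training encodings.
#'
#' @param encodings named list: animal id -> numeric matrix (one encoding per
#'   row) or numeric vector (a single encoding).
#' @param threshold maximal distance at which a query is still assigned to its
#'   nearest anchor (> 0); queries farther than this from every anchor are
#'   rejected as unknown animals or bad acquisitions.
#' @return object of class `anchor_dictionary` with fields `anchors` (matrix,
#'   one row per id), `threshold`, `counts`, `dim`.
#' @export
build_anchor_dictionary <- function(encodings, threshold) {
  if (!length(encodings) || is.null(names(encodings))) {
    stop("encodings must be a named list keyed by animal id", call. = FALSE)
  }
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  mats <- lapply(names(encodings), function(id) {
    m <- encodings[[id]]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m <- as.matrix(m)
    if (!nrow(m)) stop(sprintf("empty encoding list for id '%s'", id), call. = FALSE)
    m
  })
  dims <- vapply(mats, ncol, 1L)
  if (length(unique(dims)) != 1) {
    stop("dimension mismatch across encodings", call. = FALSE)
  }
  anchors <- do.call(rbind, lapply(mats, colMeans))
  rownames(anchors) <- names(encodings)
  counts <- vapply(mats, nrow, 1L)
  names(counts) <- names(encodings)
  structure(list(anchors = anchors, threshold = as.numeric(threshold),
                 counts = counts, dim = dims[1]),
            class = "anchor_dictionary")
}

#' Identify a query encoding against the anchor dictionary
#'
#' Assigns the id of the Euclidean-nearest anchor when its distance is within
#' the dictionary threshold; otherwise rejects (open-set behaviour signalling
#' an unknown animal or an unsuitable acquisition). Exact distance ties break
#' to the lexicographically smallest id.
#'
#' @param query numeric vector of the dictionary's dimension.
#' @param dict [build_anchor_dictionary()] result.
#' @return list with `animal_id` (`NA` when rejected), `distance` (to the
#'   nearest anchor), and logical `rejected`.
#' @export
identify_animal <- function(query, dict) {
  stopifnot(inherits(dict, "anchor_dictionary"))
  if (!nrow(dict$anchors)) stop("empty anchor dictionary", call. = FALSE)
  query <- as.numeric(query)
  if (length(query) != dict$dim) {
    stop(sprintf("query dimension %d does not match dictionary dimension %d",
                 length(query), dict$dim), call. = FALSE)
  }
  d <- sqrt(rowSums(sweep(dict$anchors, 2, query)^2))
  ids <- rownames(dict$anchors)
  best <- order(d, ids)[1]
  if (d[best] <= dict$threshold) {
    list(animal_id = ids[best], distance = unname(d[best]), rejected = FALSE)
  } else {
    list(animal_id = NA_character_, distance = unname(d[best]), rejected = TRUE)
  }
}

#' Enroll encodings for a new or existing animal
#'
#' A new id gets a fresh anchor (mean of its encodings); an existing id's
#' anchor is updated to the running mean over all encodings ever enrolled for
#' it. No other anchor changes, so the population can grow without
#' retraining.
#'
#' @param dict [build_anchor_dictionary()] result.
#' @param animal_id id to enroll.
#' @param encodings numeric matrix (rows) or single numeric vector.
#' @return updated `anchor_dictionary`.
#' @export
enroll <- function(dict, animal_id, encodings) {
  stopifnot(inherits(dict, "anchor_dictionary"))
  if (is.null(dim(encodings))) encodings <- matrix(encodings, nrow = 1)
  encodings <- as.matrix(encodings)
  if (!nrow(encodings)) stop("empty encodings", call. = FALSE)
  if (ncol(encodings) != dict$dim) {
    stop("dimension mismatch with dictionary", call. = FALSE)
  }
  animal_id <- as.character(animal_id)
  m <- nrow(encodings)
  new_sum <- colSums(encodings)
  if (animal_id %in% rownames(dict$anchors)) {
    n0 <- dict$counts[[animal_id]]
    dict$anchors[animal_id, ] <-
      (dict$anchors[animal_id, ] * n0 + new_sum) / (n0 + m)
    dict$counts[[animal_id]] <- n0 + m
  } else {
    dict$anchors <- rbind(dict$anchors, matrix(new_sum / m, nrow = 1,
                                               dimnames = list(animal_id)))
    dict$counts <- c(dict$counts, stats::setNames(m, animal_id))
  }
  dict
}

#' Serialize an anchor dictionary to JSON
#'
#' Format: `{dim, threshold, anchors: {id: [..]}, counts: {id: n}}`.
#'
#' @param dict `anchor_dictionary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_anchor_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "anchor_dictionary"))
  anchors <- lapply(seq_len(nrow(dict$anchors)),
                    function(i) unname(dict$anchors[i, ]))
  names(anchors) <- rownames(dict$anchors)
  obj <- list(dim = dict$dim, threshold = dict$threshold,
              anchors = anchors, counts = as.list(dict$counts))
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)),
             path)
  invisible(path)
}

#' Read an anchor dictionary from JSON
#'
#' @param path file written by [write_anchor_dictionary()].
#' @return `anchor_dictionary` object.
#' @export
read_anchor_dictionary <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  anchors <- do.call(rbind, obj$anchors)
  counts <- unlist(obj$counts)
  structure(list(anchors = anchors, threshold = obj$threshold,
                 counts = counts[rownames(anchors)], dim = obj$dim),
            class = "anchor_dictionary")
}

#' @export
print.anchor_dictionary <- function(x, ...) {
  cat("anchor_dictionary:", nrow(x$anchors), "animals in", x$dim,
      "dimensions, threshold", x$threshold, "\n")
  invisible(x)
}
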