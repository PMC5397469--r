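#' Standard 8x8 MEA electrode layout (corners void)
#'
#' Builds the planar layout of the 60-electrode micro-electrode array used for
#' slice recordings: electrodes sit on a square 8x8 grid with the four corner
#' positions absent. Electrode ids are two-digit column-row codes ("27" =
#' column 2, row 7), the convention printed next to each electrode in slice
#' photographs. Coordinates are in micrometres with the origin at the (void)
#' "11" position, x increasing with column and y with row.
#'
#' @param pitch Centre-to-centre electrode spacing in um (default 200).
#' @param diameter Electrode diameter in um (default 30). Metadata only.
#' @return An object of class `mea_layout`: a data.frame with columns
#'   `electrode_id`, `col`, `row`, `x`, `y` (um), ordered lexicographically by
#'   id, with attributes `pitch` and `diameter`.
#' @examples
#' lay <- mea_layout()
#' nrow(lay)                      # 60
#' "11" %in% lay$electrode_id     # FALSE: corners are void
#' @export
mea_layout <- function(pitch = 200, diameter = 30) {
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0)
    stop("`pitch` must be a single positive number (um)")
  grid <- expand.grid(col = 1:8, row = 1:8)
  id <- sprintf("%d%d", grid$col, grid$row)
  corners <- c("11", "18", "81", "88")
  keep <- !(id %in% corners)
  lay <- data.frame(
    electrode_id = id[keep],
    col = grid$col[keep],
    row = grid$row[keep],
    x = (grid$col[keep] - 1) * pitch,
    y = (grid$row[keep] - 1) * pitch,
    stringsAsFactors = FALSE
  )
  lay <- lay[order(lay$electrode_id), , drop = FALSE]
  rownames(lay) <- NULL
  attr(lay, "pitch") <- pitch
  attr(lay, "diameter") <- diameter
  class(lay) <- c("mea_layout", "data.frame")
  lay
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("MEA layout: %d electrodes, 8x8 grid minus corners, pitch %g um, diameter %g um\n",
              nrow(x), attr(x, "pitch"), attr(x, "diameter")))
  invisible(x)
}

#' Euclidean distance between two electrodes
#'
#' @param layout An [mea_layout()].
#' @param a,b Electrode ids.
#' @return Distance in um.
#' @export
electrode_distance <- function(layout, a, b) {
  ia <- match(a, layout$electrode_id)
  ib <- match(b, layout$electrode_id)
  if (anyNA(c(ia, ib)))
    stop("unknown electrode id: ", paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  sqrt((layout$x[ia] - layout$x[ib])^2 + (layout$y[ia] - layout$y[ib])^2)
}

grid_neighbors <- function(layout, a, b) {
  # 4-neighbourhood on the grid: one step along a column or a row
  ia <- match(a, layout$electrode_id)
  ib <- match(b, layout$electrode_id)
  if (anyNA(c(ia, ib))) return(FALSE)
  dc <- abs(layout$col[ia] - layout$col[ib])
  dr <- abs(layout$row[ia] - layout$row[ib])
  (dc + dr) == 1L
}

#' Region labels recognised by the pipeline
#' @keywords internal
REGION_LABELS <- c("DG", "CA3a", "CA3b", "CA3c", "CA1", "Sub", "none")

#' Construct a validated electrode-to-region map
#'
#' A region map assigns each electrode of the layout to an anatomical
#' sub-region of the slice (DG, CA3a/b/c, CA1, Sub, or "none" for electrodes
#' outside the tissue), and designates, per analysed region, the two adjacent
#' electrodes lying along the pyramidal (CA3, CA1, Sub) or granule (DG) cell
#' layer whose event parameters are averaged in region-level summaries.
#'
#' @param assignment Named character vector: electrode id -> region label.
#' @param cell_layer_pairs Named list: region key (e.g. "CA3", "CA1", "Sub",
#'   "DG") -> character vector of exactly two electrode ids. The two must be
#'   grid neighbours and both carry a label matching the key ("CA3" matches
#'   CA3a/b/c).
#' @param layout An [mea_layout()] against which ids are validated.
#' @return An object of class `region_map`.
#' @export
region_map <- function(assignment, cell_layer_pairs = list(), layout = mea_layout()) {
  assignment <- unlist(assignment)
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    stop("`assignment` must be a named vector: electrode id -> region label")
  unknown <- setdiff(names(assignment), layout$electrode_id)
  if (length(unknown))
    stop("region map names electrode id(s) not in the layout: ",
         paste(unknown, collapse = ", "))
  bad <- setdiff(unique(assignment), REGION_LABELS)
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(REGION_LABELS, collapse = ", "), ")")
  for (reg in names(cell_layer_pairs)) {
    pair <- unlist(cell_layer_pairs[[reg]])
    if (length(pair) != 2L)
      stop("cell_layer_pairs[['", reg, "']] must name exactly two electrodes, got ",
           length(pair))
    missing_ids <- setdiff(pair, names(assignment))
    if (length(missing_ids))
      stop("cell-layer pair for ", reg, " names unassigned electrode id(s): ",
           paste(missing_ids, collapse = ", "))
    labs <- assignment[pair]
    if (!all(labs == reg | startsWith(labs, reg)))
      stop("cell-layer pair for ", reg, " has labels (",
           paste(labs, collapse = ", "), ") not matching the region")
    if (!grid_neighbors(layout, pair[1], pair[2]))
      stop("cell-layer pair for ", reg, " (", paste(pair, collapse = ", "),
           ") are not grid neighbours")
  }
  structure(
    list(assignment = assignment,
         cell_layer_pairs = lapply(cell_layer_pairs, unlist)),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = REGION_LABELS))
  cat("Region map:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (length(x$cell_layer_pairs))
    cat("Cell-layer pairs:",
        paste(sprintf("%s(%s)", names(x$cell_layer_pairs),
                      vapply(x$cell_layer_pairs, paste, "", collapse = ",")),
              collapse = " "), "\n")
  invisible(x)
}

#' Region label of one or more electrodes
#' @param regions A [region_map()].
#' @param electrode_id Character vector of ids.
#' @return Character vector of labels ("none" for unassigned electrodes).
#' @export
electrode_region <- function(regions, electrode_id) {
  out <- unname(regions$assignment[electrode_id])
  out[is.na(out)] <- "none"
  out
}

#' Read a region map from JSON
#'
#' Expects a document of the form
#' `{"assignment": {"27": "CA3b", ...}, "cell_layer_pairs": {"CA3": ["17","27"], ...}}`.
#' Region maps are recording-specific (regions are assigned from the slice
#' image); the package ships one canonical map used by the simulator, see
#' [default_region_map()].
#'
#' @param path Path to the JSON file.
#' @param layout Layout used for validation.
#' @return A [region_map()].
#' @export
read_region_map <- function(path, layout = mea_layout()) {
  if (!file.exists(path)) stop("region map file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$assignment))
    stop("region map JSON lacks required key 'assignment'")
  region_map(doc$assignment,
             if (is.null(doc$cell_layer_pairs)) list() else doc$cell_layer_pairs,
             layout)
}

#' Write a region map to JSON
#' @param regions A [region_map()].
#' @param path Output path.
#' @export
write_region_map <- function(regions, path) {
  jsonlite::write_json(
    list(assignment = as.list(regions$assignment),
         cell_layer_pairs = lapply(regions$cell_layer_pairs, as.list)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The canonical fixture region map
#'
#' Loads the region map shipped with the package. It places a stereotypical
#' hippocampal slice on the array: CA3a/b in the lower-left quadrant, CA3c and
#' DG behind them (retrograde direction), CA1 along the top rows, and the
#' subiculum on the right edge; electrodes outside the tissue are "none". It
#' matches the anchors used throughout the figures of slice-on-MEA studies
#' (e.g. an electrode "27" in CA3, "41" in CA1, "54" in DG, "82" in Sub). The
#' simulator and the bundled tests use this map.
#'
#' @param layout Layout used for validation.
#' @return A [region_map()].
#' @export
default_region_map <- function(layout = mea_layout()) {
  path <- system.file("extdata", "region_map.json", package = "ictomap")
  if (path == "") stop("bundled region map not found; is the package installed?")
  read_region_map(path, layout)
}
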