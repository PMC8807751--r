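#' Electrode montages
#'
#' A montage is the ordered electrode set with 3-D unit-sphere coordinates.
#' It fixes the channel order of every downstream object (recordings,
#' trial sets, adjacency matrices) and defines the left/right mirror pairs
#' used by hemispheric asymmetry features and the frontal/posterior pairs
#' used by caudal asymmetry features.
#'
#' Coordinates use a head-centred frame: `x` increases to the subject's
#' right, `y` to the front, `z` towards the vertex, with `Cz` at (0,0,1).
#'
#' @param path text file with 4 whitespace-separated columns
#'   (name, x, y, z), no header.
#' @param mirror_pairs optional 2-column data frame (left, right electrode
#'   names) overriding the coordinate-derived pairing.
#' @param caudal_pairs optional 2-column data frame (frontal, posterior
#'   names) overriding the coordinate-derived pairing.
#' @return an object of class `eeg_montage`: a data frame with columns
#'   `name`, `x`, `y`, `z` and attributes `mirror_pairs`, `caudal_pairs`.
#' @seealso [montage_bci22()] for the built-in 22-electrode layout.
#' @export
read_montage <- function(path, mirror_pairs = NULL, caudal_pairs = NULL) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  montage(tab$name, as.matrix(tab[, c("x", "y", "z")]),
          mirror_pairs = mirror_pairs, caudal_pairs = caudal_pairs)
}

#' @param names character vector of electrode labels.
#' @param coords numeric matrix, one row per electrode, columns x, y, z.
#' @rdname read_montage
#' @export
montage <- function(names, coords, mirror_pairs = NULL, caudal_pairs = NULL) {
  coords <- as.matrix(coords)
  if (length(names) != nrow(coords)) stop2("one coordinate row per electrode required")
  if (!all(is.finite(coords))) stop2("montage coordinates must be finite")
  if (anyDuplicated(names)) stop2("duplicate electrode names")
  m <- data.frame(name = as.character(names), x = coords[, 1],
                  y = coords[, 2], z = coords[, 3], stringsAsFactors = FALSE)
  class(m) <- c("eeg_montage", "data.frame")
  attr(m, "mirror_pairs") <- mirror_pairs %||% derive_pairs(m, axis = "x")
  attr(m, "caudal_pairs") <- caudal_pairs %||% derive_pairs(m, axis = "y")
  validate_pairs(m)
  m
}

# Pairs each off-axis electrode with the nearest electrode to its
# reflection through the given axis.  Electrodes on the axis (|coord| below
# tol) stay unpaired.  For axis "x" the pair is ordered (left, right);
# for "y", (frontal, posterior).
derive_pairs <- function(m, axis = c("x", "y"), tol = 1e-6) {
  axis <- match.arg(axis)
  xyz <- as.matrix(m[, c("x", "y", "z")])
  a <- xyz[, if (axis == "x") 1L else 2L]
  first <- which(a < -tol)   # left (x) / posterior handled below
  if (axis == "y") first <- which(a > tol)   # frontal side leads the pair
  out <- NULL
  for (i in first) {
    refl <- xyz[i, ]
    refl[if (axis == "x") 1L else 2L] <- -refl[if (axis == "x") 1L else 2L]
    d <- sqrt(colSums((t(xyz) - refl)^2))
    d[i] <- Inf
    j <- which.min(d)
    if (d[j] < 0.3) out <- rbind(out, c(m$name[i], m$name[j]))
  }
  if (is.null(out)) return(data.frame(a = character(), b = character()))
  df <- data.frame(a = out[, 1], b = out[, 2], stringsAsFactors = FALSE)
  names(df) <- if (axis == "x") c("left", "right") else c("frontal", "posterior")
  df
}

validate_pairs <- function(m) {
  for (nm in c("mirror_pairs", "caudal_pairs")) {
    p <- attr(m, nm)
    if (is.null(p) || nrow(p) == 0) next
    if (!all(unlist(p) %in% m$name)) stop2(nm, " references unknown electrodes")
    if (any(p[[1]] == p[[2]])) stop2(nm, " pairs an electrode with itself")
  }
  invisible(m)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes, %d mirror pairs, %d caudal pairs\n",
              nrow(x), nrow(attr(x, "mirror_pairs")),
              nrow(attr(x, "caudal_pairs"))))
  invisible(x)
}

#' Built-in 22-electrode motor-cortex montage
#'
#' The 22-channel layout used by four-class motor-imagery recordings
#' (Fz, FC/C/CP rows, P row, POz), with unit-sphere coordinates derived
#' from 10-20 system angles.  Row order here is the canonical channel
#' order for all bundled examples.
#'
#' @return an `eeg_montage` with 22 electrodes.
#' @export
montage_bci22 <- function() {
  # (name, midline angle a [deg, + = front], lateral angle b [deg, + = right])
  spec <- list(
    c("Fz",   54,   0),
    c("FC3",  27, -36), c("FC1",  27, -18), c("FCz", 27, 0),
    c("FC2",  27,  18), c("FC4",  27,  36),
    c("C5",    0, -54), c("C3",    0, -36), c("C1",   0, -18), c("Cz", 0, 0),
    c("C2",    0,  18), c("C4",    0,  36), c("C6",   0,  54),
    c("CP3", -27, -36), c("CP1", -27, -18), c("CPz", -27, 0),
    c("CP2", -27,  18), c("CP4", -27,  36),
    c("P1",  -54, -18), c("Pz",  -54,   0), c("P2", -54, 18),
    c("POz", -72,   0))
  nm <- vapply(spec, `[`, character(1), 1)
  a <- as.numeric(vapply(spec, `[`, character(1), 2)) * pi / 180
  b <- as.numeric(vapply(spec, `[`, character(1), 3)) * pi / 180
  coords <- cbind(x = sin(b), y = sin(a) * cos(b), z = cos(a) * cos(b))
  montage(nm, coords)
}
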