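#' 64-channel montage on the unit sphere
#'
#' Builds the 64-electrode BioSemi-style 10-10 montage used throughout the
#' package. Positions are constructed geometrically on an idealized
#' spherical head (vertex at +z, nose at +y, left at -x): the outer ring
#' (Fpz..Oz over Fp1/AF7/F7/FT7/T7/TP7/P7/PO7/O1 and mirrored) lies at 72
#' degrees inclination in 18-degree azimuthal steps, midline electrodes at
#' 18-degree inclination steps, and each intermediate row (AF, F, FC, C,
#' CP, P, PO) is spaced equally in angle along the circle through its two
#' ring electrodes and its midline electrode. P9/P10 and Iz sit on the
#' equator below P7/P8 and Oz.
#'
#' @return An object of class `montage`: a data frame with columns
#'   `label`, `x`, `y`, `z` (unit-norm positions).
#' @examples
#' m <- make_montage()
#' nrow(m)        # 64
#' range(sqrt(m$x^2 + m$y^2 + m$z^2))
#' @export
make_montage <- function() {
  deg <- pi / 180
  # position on the 72-degree ring at azimuth psi (degrees from nose,
  # positive towards the left ear)
  ring <- function(psi) sph_pos(72, psi)
  mid <- function(incl_front) {
    # inclination measured from vertex along the midline; negative = back
    th <- abs(incl_front)
    s <- if (incl_front >= 0) 1 else -1
    c(0, s * sin(th * deg), cos(th * deg))
  }

  pos <- list()
  add <- function(label, p) pos[[label]] <<- p

  # midline
  add("Fpz", mid(72)); add("AFz", mid(54)); add("Fz", mid(36))
  add("FCz", mid(18)); add("Cz", c(0, 0, 1)); add("CPz", mid(-18))
  add("Pz", mid(-36)); add("POz", mid(-54)); add("Oz", mid(-72))
  add("Iz", c(0, -1, 0))

  # outer ring, 18-degree steps from the nose
  ring_left <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
                 TP7 = 108, P7 = 126, PO7 = 144, O1 = 162)
  for (lab in names(ring_left)) add(lab, ring(ring_left[[lab]]))
  for (lab in names(ring_left)) {
    rlab <- sub("7$", "8", sub("1$", "2", lab))
    add(rlab, mirror_x(ring(ring_left[[lab]])))
  }

  # equator electrodes below P7/P8
  add("P9", sph_pos(90, 126)); add("P10", mirror_x(sph_pos(90, 126)))

  # intermediate rows: equal angular spacing along the circle through
  # (left ring electrode, midline electrode, right ring electrode)
  rows <- list(
    list(left = "AF7", mid = "AFz", labels = c("AF3")),
    list(left = "F7",  mid = "Fz",  labels = c("F5", "F3", "F1")),
    list(left = "FT7", mid = "FCz", labels = c("FC5", "FC3", "FC1")),
    list(left = "T7",  mid = "Cz",  labels = c("C5", "C3", "C1")),
    list(left = "TP7", mid = "CPz", labels = c("CP5", "CP3", "CP1")),
    list(left = "P7",  mid = "Pz",  labels = c("P5", "P3", "P1")),
    list(left = "PO7", mid = "POz", labels = c("PO3"))
  )
  for (row in rows) {
    p1 <- pos[[row$left]]; pm <- pos[[row$mid]]
    k <- length(row$labels)
    fr <- seq_len(k) / (k + 1)
    pts <- circle_interp(p1, pm, mirror_x(p1), fr)
    for (i in seq_len(k)) {
      add(row$labels[i], pts[i, ])
      add(lateral_mirror_label(row$labels[i]), mirror_x(pts[i, ]))
    }
  }

  # canonical BioSemi A1..B32 ordering
  order64 <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
  stopifnot(setequal(order64, names(pos)))
  xyz <- t(vapply(order64, function(l) pos[[l]], numeric(3)))
  out <- data.frame(label = order64, x = xyz[, 1], y = xyz[, 2],
                    z = xyz[, 3], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("montage", "data.frame")
  out
}

sph_pos <- function(incl_deg, psi_deg) {
  # inclination from vertex; azimuth psi from nose towards the left
  deg <- pi / 180
  th <- incl_deg * deg
  ps <- psi_deg * deg
  c(-sin(th) * sin(ps), sin(th) * cos(ps), cos(th))
}

mirror_x <- function(p) c(-p[1], p[2], p[3])

lateral_mirror_label <- function(label) {
  num <- as.integer(sub("^[A-Za-z]+", "", label))
  paste0(sub("[0-9]+$", "", label), num + 1L)
}

# points on the circle through p1, pm, p2 (all on the unit sphere), at the
# given fractions of the arc from p1 to pm
circle_interp <- function(p1, pm, p2, fracs) {
  n <- pracma_cross(pm - p1, p2 - p1)
  n <- n / sqrt(sum(n^2))
  # circle centre: intersection of the plane with the perpendicular
  # bisector planes of (p1, pm) and (p1, p2)
  a <- rbind(n, pm - p1, p2 - p1)
  b <- c(sum(n * p1),
         sum((pm - p1) * (pm + p1)) / 2,
         sum((p2 - p1) * (p2 + p1)) / 2)
  o <- solve(a, b)
  v1 <- p1 - o
  vm <- pm - o
  r <- sqrt(sum(v1^2))
  e1 <- v1 / r
  e2 <- pracma_cross(n, e1)
  ang <- atan2(sum(vm * e2), sum(vm * e1))
  t(vapply(fracs, function(fr) {
    o + r * (cos(fr * ang) * e1 + sin(fr * ang) * e2)
  }, numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("montage: %d electrodes on the unit sphere\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Subset a montage by channel labels
#'
#' Convenience for scaled-down analyses: keeps the given labels (in the
#' given order) with their spherical positions.
#'
#' @param montage a [make_montage()] result.
#' @param labels channel labels to keep.
#' @return A `montage` with `length(labels)` rows.
#' @export
subset_montage <- function(montage, labels) {
  stopifnot(inherits(montage, "montage"))
  miss <- setdiff(labels, montage$label)
  if (length(miss))
    stop("unknown channel labels: ", paste(miss, collapse = ", "))
  out <- montage[match(labels, montage$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("montage", "data.frame")
  out
}
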