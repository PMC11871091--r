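# Binary morphology wrappers over the C++ kernels. All operate on logical
# matrices; the structuring element is a Euclidean disk.

disk_offsets <- function(radius) {
  r <- max(1L, as.integer(round(radius)))
  g <- expand.grid(di = -r:r, dj = -r:r)
  g <- g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

mdilate <- function(mask, radius) {
  cpp_dilate(mask, disk_offsets(radius))
}

merode <- function(mask, radius) {
  cpp_erode(mask, disk_offsets(radius))
}

mclose <- function(mask, radius) {
  off <- disk_offsets(radius)
  cpp_erode(cpp_dilate(mask, off), off)
}

label_components <- function(mask, connectivity = 8) {
  cpp_label_components(mask, as.integer(connectivity))
}

largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# fill interior holes: background components not touching the image border
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, 4)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- bg & !(lab %in% border)
  dim(hole) <- dim(mask)
  mask | hole
}
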