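#' Describe a simulation container
#'
#' A box descriptor couples the geometric parameters of the container with
#' the shape and periodicity codes of the standard. Rectangular-cuboid and
#' triclinic containers are described by three box vectors and an origin;
#' spheres by radius and center; cylinders by radius, height, axis and
#' center.
#'
#' @param shape Shape label or code (see [code_books()]).
#' @param periodic_dims Character vector of periodic dimensions, subset of
#'   `c("x","y","z")`; for triclinic cells these refer to box vectors
#'   1, 2, 3.
#' @param vectors 3x3 numeric matrix of row-wise box vectors (Angstrom);
#'   required for cuboid/triclinic. For a cuboid, pass edge lengths via
#'   `diag(c(a,b,c))`.
#' @param origin Numeric length-3 origin (cuboid/triclinic) or center
#'   (sphere/cylinder), Angstrom. Default `c(0,0,0)`.
#' @param radius Sphere/cylinder radius (Angstrom).
#' @param height Cylinder height (Angstrom).
#' @param axis Cylinder axis as 1 (x), 2 (y) or 3 (z).
#' @return An object of class `box_descriptor`.
#' @export
#' @examples
#' box_descriptor("rectangular_cuboid", c("x", "y", "z"),
#'                vectors = diag(c(20, 20, 20)))
box_descriptor <- function(shape, periodic_dims = character(),
                           vectors = NULL, origin = c(0, 0, 0),
                           radius = NULL, height = NULL, axis = 3L) {
  shape_code <- if (is.numeric(shape)) as.integer(shape) else {
    encode("box_shape", shape)
  }
  periodicity_code <- encode_periodicity(periodic_dims, shape_code)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  if (shape_code %in% c(1L, 4L)) {
    if (is.null(vectors)) stop("vectors required for cuboid/triclinic box",
                               call. = FALSE)
    vectors <- matrix(as.numeric(vectors), 3L, 3L)
  } else if (shape_code == 2L) {
    if (is.null(radius) || radius <= 0) stop("sphere requires radius > 0",
                                             call. = FALSE)
  } else if (shape_code == 3L) {
    if (is.null(radius) || radius <= 0 || is.null(height) || height <= 0) {
      stop("cylinder requires radius > 0 and height > 0", call. = FALSE)
    }
    axis <- as.integer(axis)
    if (!axis %in% 1:3) stop("cylinder axis must be 1, 2 or 3",
                             call. = FALSE)
    # a periodic cylinder is periodic along its axis only
    if (periodicity_code != 0L) {
      ax_of_code <- c(3L, 2L, 1L)[periodicity_code] # codes 1,2,3 = z,y,x
      if (ax_of_code != axis) {
        stop("cylinder periodic dimension must coincide with its axis",
             call. = FALSE)
      }
    }
  }
  structure(
    list(
      shape_code = shape_code, periodicity_code = periodicity_code,
      vectors = vectors, origin = origin,
      radius = if (is.null(radius)) NULL else as.numeric(radius),
      height = if (is.null(height)) NULL else as.numeric(height),
      axis = as.integer(axis)
    ),
    class = "box_descriptor"
  )
}

#' @export
print.box_descriptor <- function(x, ...) {
  cat(sprintf(
    "<box_descriptor> shape=%s (%d) periodicity=%s (%d)\n",
    decode("box_shape", x$shape_code), x$shape_code,
    decode("box_periodicity", x$periodicity_code), x$periodicity_code
  ))
  invisible(x)
}

#' Encode a box descriptor as the standard's 12-vector
#'
#' The order is box vector 1, box vector 2, box vector 3, then the origin,
#' each as x, y, z. For curved containers this package uses the following
#' documented convention (it is this package's own; other implementations
#' define their own layouts): sphere -- element 1 holds the radius,
#' elements 2-9 are zero, elements 10-12 hold the center; cylinder --
#' element 1 radius, element 2 height, element 3 axis index (1/2/3),
#' elements 4-9 zero, elements 10-12 center.
#'
#' @param box A [box_descriptor()].
#' @return Numeric vector of length 12.
#' @export
encode_box <- function(box) {
  stopifnot(inherits(box, "box_descriptor"))
  .check_shape_periodicity(box$shape_code, box$periodicity_code)
  if (box$shape_code %in% c(1L, 4L)) {
    c(t(box$vectors)[1:3], box$vectors[2, ], box$vectors[3, ], box$origin)
  } else if (box$shape_code == 2L) {
    c(box$radius, rep(0, 8), box$origin)
  } else {
    c(box$radius, box$height, box$axis, rep(0, 6), box$origin)
  }
}

#' Decode a 12-vector into a box descriptor
#'
#' Exact inverse of [encode_box()] given the shape and periodicity codes
#' (stored in the simulation tier, which must be cross-referenced to
#' interpret the box values).
#'
#' @param box12 Numeric vector of length 12.
#' @param shape_code Integer box-shape code.
#' @param periodicity_code Integer periodicity code. Default 0.
#' @return A [box_descriptor()].
#' @export
decode_box <- function(box12, shape_code, periodicity_code = 0L) {
  box12 <- as.numeric(box12)
  if (length(box12) != 12L) stop("box must have exactly 12 elements",
                                 call. = FALSE)
  shape_code <- as.integer(shape_code)
  dims <- .periodicity_dims(periodicity_code)
  if (shape_code %in% c(1L, 4L)) {
    box_descriptor(shape_code, dims,
                   vectors = matrix(box12[1:9], 3L, 3L, byrow = TRUE),
                   origin = box12[10:12])
  } else if (shape_code == 2L) {
    box_descriptor(shape_code, dims, radius = box12[1],
                   origin = box12[10:12])
  } else if (shape_code == 3L) {
    box_descriptor(shape_code, dims, radius = box12[1], height = box12[2],
                   axis = as.integer(box12[3]), origin = box12[10:12])
  } else {
    stop(sprintf("invalid box_shape code %d", shape_code), call. = FALSE)
  }
}

# periodicity code -> character dims
.periodicity_dims <- function(code) {
  switch(as.character(as.integer(code)),
    "0" = character(), "1" = "z", "2" = "y", "3" = "x",
    "4" = c("y", "z"), "5" = c("x", "z"), "6" = c("x", "y"),
    "7" = c("x", "y", "z"),
    stop(sprintf("invalid box_periodicity code %s", code), call. = FALSE)
  )
}

# largest linear extent of the container, used by the ghost convention
.box_extent <- function(box) {
  if (box$shape_code %in% c(1L, 4L)) {
    max(sqrt(rowSums(box$vectors^2)))
  } else if (box$shape_code == 2L) {
    2 * box$radius
  } else {
    max(2 * box$radius, box$height)
  }
}
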