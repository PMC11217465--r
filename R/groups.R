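#' Construct an element of the p4 / p4m point group
#'
#' An element is a pair (mirror, rotation): `mirror` is 0 or 1 (reflection
#' about the vertical axis, i.e. a left-right flip) and `rotation` counts
#' counterclockwise quarter turns (0--3). The element acts on an image by
#' applying the mirror first, then the rotation. `(0, 0)` is the identity.
#'
#' @param mirror integer flag in `{0, 1}`.
#' @param rotation integer in `{0, 1, 2, 3}`.
#' @return An object of class `"group_element"`.
#' @examples
#' group_element(0, 1)  # 90 degree counterclockwise rotation
#' @export
group_element <- function(mirror = 0L, rotation = 0L) {
  mirror <- as.integer(mirror)
  rotation <- as.integer(rotation)
  if (length(mirror) != 1L || is.na(mirror) || !(mirror %in% c(0L, 1L)))
    stop("'mirror' must be 0 or 1")
  if (length(rotation) != 1L || is.na(rotation) || !(rotation %in% 0:3))
    stop("'rotation' must be an integer in 0..3")
  structure(list(mirror = mirror, rotation = rotation), class = "group_element")
}

#' @export
print.group_element <- function(x, ...) {
  cat(sprintf("<group element: mirror=%d, rotation=%d (%d deg ccw)>\n",
              x$mirror, x$rotation, 90L * x$rotation))
  invisible(x)
}

#' @export
format.group_element <- function(x, ...) {
  sprintf("(m=%d,r=%d)", x$mirror, x$rotation)
}

rot90_ccw <- function(x) t(x[, ncol(x):1, drop = FALSE])

#' Apply a group element to a square image
#'
#' Exact index remapping (flip/transpose composition), no interpolation:
#' the mirror (left-right flip) is applied first, then `rotation`
#' counterclockwise quarter turns. Even-sized arrays rotate about the array
#' centre, so no centre pixel is required. Output values are a permutation
#' of the input values.
#'
#' @param g a [group_element()].
#' @param image a square numeric matrix.
#' @return The transformed matrix, same dimensions as the input.
#' @examples
#' x <- matrix(1:9, 3, 3)
#' g_act(group_element(0, 1), x)
#' @export
g_act <- function(g, image) {
  if (!inherits(g, "group_element")) stop("'g' must be a group_element")
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("'image' must be a square matrix (90 degree rotations must preserve shape)")
  y <- if (g$mirror == 1L) image[, ncol(image):1, drop = FALSE] else image
  r <- g$rotation
  while (r > 0L) {
    y <- rot90_ccw(y)
    r <- r - 1L
  }
  y
}

element_key <- function(m, r) paste0(m, ".", r)

#' Construct the p4 or p4m symmetry group
#'
#' Builds the point group of quarter-turn rotations (`"p4"`, order 4) or
#' rotations plus a reflection (`"p4m"`, order 8) together with its
#' composition table and inverses. Elements are held in canonical order:
#' the four unmirrored rotations by increasing angle, then (for p4m) the
#' four mirrored ones. The composition table is derived from the exact
#' pixel action on a probe array, so every downstream consumer shares one
#' convention: entry `[i, j]` is the index of "apply element j, then
#' element i".
#'
#' @param name `"p4"` or `"p4m"`.
#' @return An object of class `"symmetry_group"` with fields `name`,
#'   `elements` (list of [group_element()]), `order`, `composition_table`
#'   (order x order integer matrix of element indices) and `inverses`
#'   (integer vector).
#' @examples
#' G <- symmetry_group("p4m")
#' G$order
#' @export
symmetry_group <- function(name = c("p4", "p4m")) {
  name <- match.arg(name)
  mirrors <- if (name == "p4m") c(0L, 1L) else 0L
  elements <- list()
  for (m in mirrors) for (r in 0:3) elements[[length(elements) + 1L]] <- group_element(m, r)
  n <- length(elements)

  # probe with an asymmetric array: every element acts as a distinct permutation
  probe <- matrix(seq_len(25), 5, 5)
  acted <- lapply(elements, g_act, image = probe)
  sig <- vapply(acted, function(a) paste(a, collapse = ","), character(1))
  if (anyDuplicated(sig)) stop("internal error: group elements not distinguished by probe")

  tab <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    composed <- g_act(elements[[i]], acted[[j]])  # apply j, then i
    k <- match(paste(composed, collapse = ","), sig)
    if (is.na(k)) stop("internal error: composition left the group")
    tab[i, j] <- k
  }
  id <- match(element_key(0L, 0L), vapply(elements, function(e) element_key(e$mirror, e$rotation), character(1)))
  inv <- vapply(seq_len(n), function(i) which(tab[i, ] == id), integer(1))

  structure(list(name = name, elements = elements, order = n,
                 composition_table = tab, inverses = inv,
                 identity_index = id),
            class = "symmetry_group")
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat(sprintf("<symmetry group %s: order %d>\n", x$name, x$order))
  cat("elements:", paste(vapply(x$elements, format, character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Index of a group element within a group's canonical ordering
#'
#' @param g a [group_element()].
#' @param group a [symmetry_group()].
#' @return Integer index into `group$elements`.
#' @export
element_index <- function(g, group) {
  if (!inherits(g, "group_element")) stop("'g' must be a group_element")
  if (!inherits(group, "symmetry_group")) stop("'group' must be a symmetry_group")
  keys <- vapply(group$elements, function(e) element_key(e$mirror, e$rotation), character(1))
  i <- match(element_key(g$mirror, g$rotation), keys)
  if (is.na(i)) stop(sprintf("element %s is not in group %s", format(g), group$name))
  i
}

#' Compose two group elements
#'
#' Returns the element equal to "apply `h`, then `g`" under the package's
#' mirror-then-rotate action convention.
#'
#' @param g,h [group_element()]s belonging to `group`.
#' @param group a [symmetry_group()].
#' @return A [group_element()].
#' @examples
#' G <- symmetry_group("p4")
#' g_compose(group_element(0, 1), group_element(0, 1), G)  # 180 degrees
#' @export
g_compose <- function(g, h, group) {
  i <- element_index(g, group)
  j <- element_index(h, group)
  group$elements[[group$composition_table[i, j]]]
}

#' Invert a group element
#'
#' @param g a [group_element()] belonging to `group`.
#' @param group a [symmetry_group()].
#' @return The [group_element()] `g^-1` with
#'   `g_compose(g, g_inverse(g, G), G)` the identity.
#' @export
g_inverse <- function(g, group) {
  i <- element_index(g, group)
  group$elements[[group$inverses[i]]]
}
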