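# Z2 persistent homology: boundary-matrix reduction to barcodes, and an
# exhaustive rank-invariant oracle for small bifiltrations.

new_barcode <- function(dimension, birth, death) {
  structure(data.frame(dimension = as.integer(dimension),
                       birth = as.numeric(birth),
                       death = as.numeric(death)),
            class = c("barcode", "data.frame"))
}

#' Persistence barcode of a filtered complex
#'
#' Standard column reduction of the Z2 boundary matrix in filtration order.
#' Within equal entry values simplices are ordered by dimension then
#' lexicographic vertex order, which makes the reduction deterministic; the
#' barcode itself is independent of tie-breaking. Bars of zero length are
#' discarded. H0 deaths follow the elder rule; essential classes are
#' reported with `death = Inf` (a Rips filtration that is connected at the
#' truncation scale yields exactly one infinite H0 bar).
#'
#' @param fc a [filtered_complex()] (monotone; validated on construction).
#' @param dims homology dimensions to compute, subset of `c(0, 1)`.
#' @return a `barcode`: data frame with columns `dimension`, `birth`,
#'   `death` (possibly `Inf`).
#' @export
compute_barcode <- function(fc, dims = c(0L, 1L)) {
  if (!inherits(fc, "filtered_complex")) stop("`fc` must be a filtered_complex")
  validate_monotone(fc)
  dims <- as.integer(dims)
  if (!all(dims %in% c(0L, 1L))) stop("only dimensions 0 and 1 are supported")
  r <- cpp_barcode(fc$n_vertices, fc$vertex_values, fc$edges, fc$edge_values,
                   fc$triangle_edges, fc$triangle_values,
                   want_h0 = 0L %in% dims, want_h1 = 1L %in% dims)
  new_barcode(
    dimension = c(rep(0L, length(r$h0_birth)), rep(1L, length(r$h1_birth))),
    birth = c(r$h0_birth, r$h1_birth),
    death = c(r$h0_death, r$h1_death))
}

#' Length of the longest finite bar
#'
#' The headline one-parameter statistic: the longest bar tracks the most
#' prominent loop (for `dim = 1`) in the cloud, e.g. the ring formed by
#' macrophages around a spheroid.
#'
#' @param bc a barcode from [compute_barcode()].
#' @param dim homology dimension (default 1).
#' @return max over finite bars of `death - birth`; 0 if there are none.
#' @export
longest_bar <- function(bc, dim = 1L) {
  sel <- bc$dimension == dim & is.finite(bc$death)
  if (!any(sel)) return(0)
  max(bc$death[sel] - bc$birth[sel])
}

#' Rank invariant of a bifiltration by explicit Z2 linear algebra
#'
#' Computes the rank of the map H(K_a) -> H(K_b) induced by inclusion, for
#' grades a <= b (coordinatewise, normalized units), directly from cycle and
#' boundary spaces: rank = dim([Z_a | B_b]) - dim(B_b), with the cycle space
#' Z_a obtained as the Z2 nullspace of the vertex-edge boundary matrix of
#' K_a and the boundary space B_b as the column space of the edge-triangle
#' boundary matrix of K_b. This is a verification oracle for small
#' complexes, deliberately independent of the barcode reduction and of the
#' diagonal slicing used in production.
#'
#' @param bif a `bifiltered_complex` (intended for clouds of ~25 points or
#'   fewer).
#' @param a,b length-2 grades with `a <= b` coordinatewise.
#' @param dim homology dimension, 0 or 1 (default 1).
#' @return integer rank; for `a == b` this is the Betti number at `a`.
#' @export
rank_invariant <- function(bif, a, b, dim = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(a > b)) stop("grades must satisfy a <= b coordinatewise")
  in_grade <- function(g, p) g[, 1] <= p[1] & g[, 2] <= p[2]
  va <- in_grade(bif$vertex_grades, a); vb <- in_grade(bif$vertex_grades, b)
  ea <- which(in_grade(bif$edge_grades, a))
  eb <- which(in_grade(bif$edge_grades, b))
  tb <- which(in_grade(bif$triangle_grades, b))
  if (dim == 0L) {
    # components of K_b that contain at least one vertex of K_a
    parent <- seq_len(bif$n_vertices)
    find <- function(v) { while (parent[v] != v) { parent[v] <<- parent[parent[v]]; v <- parent[v] }; v }
    for (e in eb) {
      ra <- find(bif$edges[e, 1]); rb <- find(bif$edges[e, 2])
      if (ra != rb) parent[rb] <- ra
    }
    return(length(unique(vapply(which(va), find, integer(1)))))
  }
  if (dim != 1L) stop("only dimensions 0 and 1 are supported")
  if (length(ea) == 0L) return(0L)
  # cycle space of K_a: nullspace of the vertex-edge boundary matrix
  d1a_cols <- lapply(ea, function(e) bif$edges[e, ])
  z_basis <- cpp_z2_nullspace(d1a_cols, bif$n_vertices)
  if (length(z_basis) == 0L) return(0L)
  # express everything over the edges of K_b
  row_of <- integer(nrow(bif$edges)); row_of[eb] <- seq_along(eb)
  z_cols <- lapply(z_basis, function(supp) row_of[ea[supp]])
  d2b_cols <- lapply(tb, function(s) row_of[bif$triangle_edges[s, ]])
  rank_b <- if (length(d2b_cols) > 0L) cpp_z2_rank(d2b_cols, length(eb)) else 0L
  rank_zb <- cpp_z2_rank(c(z_cols, d2b_cols), length(eb))
  rank_zb - rank_b
}

#' Serialize a barcode to plain text
#'
#' One line per bar: `dim birth death`, with the token `inf` for essential
#' classes.
#'
#' @param bc a barcode.
#' @param path output file path.
#' @export
write_barcode <- function(bc, path) {
  death <- ifelse(is.finite(bc$death), format(bc$death, digits = 17), "inf")
  writeLines(paste(bc$dimension, format(bc$birth, digits = 17), death), path)
  invisible(path)
}

#' Read a barcode written by [write_barcode()]
#' @param path input file path.
#' @return a barcode.
#' @export
read_barcode <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_barcode(integer(0), numeric(0), numeric(0)))
  parts <- strsplit(lines, "\\s+")
  new_barcode(
    dimension = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    birth = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    death = vapply(parts, function(p) if (p[3] == "inf") Inf else as.numeric(p[3]),
                   numeric(1)))
}
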