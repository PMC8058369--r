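#' Define a layered simulation volume
#'
#' The model volume is a rectangular column: x runs transversally (the
#' direction parallel fibers travel), y sagittally, z vertically. The column
#' is split bottom-up into a deep-nuclei region, the granular layer, a
#' Purkinje-cell monolayer, and the molecular layer. Layer boundaries tile
#' \code{[0, z_extent]}.
#'
#' @param x_extent,y_extent,z_extent Volume extents in um. The reference
#'   model uses 400 x 400 x 900.
#' @param layers Named list of z-intervals (two-element numeric vectors)
#'   with entries \code{dcn}, \code{granular}, \code{pc}, \code{molecular}.
#'   The \code{pc} entry is the monolayer interval; Purkinje somata are
#'   placed at its midplane with +/- jitter.
#' @return An object of class \code{volume_spec}.
#' @export
#' @examples
#' volume_spec()               # reference 400 x 400 x 900 um column
#' volume_spec(x_extent = 800) # doubled transversal footprint
volume_spec <- function(x_extent = 400, y_extent = 400, z_extent = 900,
                        layers = list(
                          dcn = c(0, 600),
                          granular = c(600, 750),
                          pc = c(750, 760),
                          molecular = c(760, 900)
                        )) {
  if (x_extent <= 0 || y_extent <= 0 || z_extent <= 0) {
    stop("volume extents must be positive", call. = FALSE)
  }
  need <- c("dcn", "granular", "pc", "molecular")
  if (!identical(sort(names(layers)), sort(need))) {
    stop("layers must be named ", paste(need, collapse = ", "), call. = FALSE)
  }
  b <- layers[need]
  lo <- vapply(b, `[`, numeric(1), 1L)
  hi <- vapply(b, `[`, numeric(1), 2L)
  if (any(hi <= lo)) stop("layer intervals must have positive height", call. = FALSE)
  if (lo[[1]] != 0 || hi[[length(hi)]] != z_extent ||
      any(abs(hi[-length(hi)] - lo[-1]) > 1e-9)) {
    stop("layer intervals must tile [0, z_extent] bottom-to-top", call. = FALSE)
  }
  structure(
    list(x_extent = x_extent, y_extent = y_extent, z_extent = z_extent,
         layers = b),
    class = "volume_spec"
  )
}

#' @export
print.volume_spec <- function(x, ...) {
  cat(sprintf("<volume_spec> %g x %g x %g um\n",
              x$x_extent, x$y_extent, x$z_extent))
  for (nm in names(x$layers)) {
    cat(sprintf("  %-9s [%g, %g)\n", nm, x$layers[[nm]][1], x$layers[[nm]][2]))
  }
  invisible(x)
}

# which layer each cell type lives in
type_layer <- function() {
  c(MF = "granular", GrC = "granular", GoC = "granular", PC = "pc",
    SC = "molecular", BC = "molecular", DCN = "dcn")
}

#' Population specification scaled to a footprint
#'
#' Cell counts scale linearly with the footprint area relative to the
#' reference 400 x 400 um footprint; the IO is a single aspatial spike
#' source and never scales. Counts are rounded to the nearest integer but
#' kept at >= 1 whenever the reference count is positive, so miniature
#' fixtures retain every population.
#'
#' @param volume A [volume_spec()].
#' @param counts Named vector of counts at the reference footprint
#'   (default [reference_counts()]).
#' @param scale Extra multiplicative factor on counts (used by fixtures).
#' @return Tibble with columns \code{cell_type}, \code{n}, \code{layer}.
#' @export
#' @examples
#' population_spec(volume_spec())                  # reference counts
#' population_spec(volume_spec(x_extent = 800))    # 2x footprint, 2x counts
population_spec <- function(volume, counts = reference_counts(), scale = 1) {
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  area_factor <- (volume$x_extent * volume$y_extent) / (400 * 400)
  types <- cell_type_order()
  counts <- counts[types]
  lay <- type_layer()
  n <- unname(vapply(types, function(tp) {
    n0 <- counts[[tp]]
    if (tp == "IO") return(as.integer(n0 > 0))
    k <- as.integer(round(n0 * area_factor * scale))
    if (n0 > 0L && k < 1L) 1L else k
  }, integer(1)))
  tibble::tibble(
    cell_type = types,
    n = n,
    layer = ifelse(types == "IO", NA_character_, unname(lay[types]))
  )
}

#' Place all populations in the volume
#'
#' Cells are placed uniformly at random inside their layer's slab. Purkinje
#' cells are instead laid out on a near-regular 2-D grid at the monolayer
#' midplane with small positional jitter (+/- 5 um in z), guaranteeing a
#' monolayer. Mossy-fiber "positions" are glomerular terminal positions in
#' the granular layer. The IO has no position.
#'
#' Global neuron ids are assigned as contiguous 1-based blocks in canonical
#' type order (MF, GrC, GoC, PC, SC, BC, DCN, IO); \code{local_id} is
#' 0-based within type.
#'
#' @param volume A [volume_spec()].
#' @param pops Tibble from [population_spec()].
#' @param seed Integer seed; placement is deterministic given the seed.
#' @return A \code{placement} object: tibble with columns \code{cell_type},
#'   \code{local_id}, \code{id}, \code{x}, \code{y}, \code{z}, plus
#'   attributes \code{volume} and \code{id_ranges}.
#' @export
#' @examples
#' vol <- volume_spec()
#' pl <- place_populations(vol, population_spec(vol, scale = 0.01), seed = 1)
#' dplyr::count(pl, cell_type)
place_populations <- function(volume, pops, seed) {
  stopifnot(inherits(volume, "volume_spec"))
  if (any(pops$n < 0)) stop("counts must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  out <- vector("list", nrow(pops))
  for (i in seq_len(nrow(pops))) {
    tp <- pops$cell_type[[i]]
    n <- pops$n[[i]]
    if (n == 0L) {
      out[[i]] <- tibble::tibble(cell_type = character(), local_id = integer(),
                                 x = numeric(), y = numeric(), z = numeric())
      next
    }
    if (tp == "IO") {
      out[[i]] <- tibble::tibble(cell_type = tp, local_id = seq_len(n) - 1L,
                                 x = NA_real_, y = NA_real_, z = NA_real_)
      next
    }
    lay <- volume$layers[[pops$layer[[i]]]]
    if (tp == "PC") {
      xy <- pc_grid(n, volume$x_extent, volume$y_extent)
      zmid <- mean(lay)
      z <- zmid + stats::runif(n, -5, 5)
      out[[i]] <- tibble::tibble(cell_type = tp, local_id = seq_len(n) - 1L,
                                 x = xy$x, y = xy$y, z = z)
    } else {
      out[[i]] <- tibble::tibble(
        cell_type = tp, local_id = seq_len(n) - 1L,
        x = stats::runif(n, 0, volume$x_extent),
        y = stats::runif(n, 0, volume$y_extent),
        z = stats::runif(n, lay[1], lay[2])
      )
    }
  }
  pl <- dplyr::bind_rows(out)
  pl <- pl[order(match(pl$cell_type, cell_type_order()), pl$local_id), ]
  pl$id <- seq_len(nrow(pl))
  pl <- pl[, c("cell_type", "local_id", "id", "x", "y", "z")]
  ranges <- id_ranges_from(pl)
  structure(tibble::as_tibble(pl),
            volume = volume, id_ranges = ranges,
            class = c("placement", class(pl)))
}

# near-square grid covering the footprint, first n cell centres, jittered
pc_grid <- function(n, lx, ly) {
  nx <- ceiling(sqrt(n * lx / ly))
  ny <- ceiling(n / nx)
  gx <- (seq_len(nx) - 0.5) * lx / nx
  gy <- (seq_len(ny) - 0.5) * ly / ny
  g <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  jx <- stats::runif(n, -0.1, 0.1) * lx / nx
  jy <- stats::runif(n, -0.1, 0.1) * ly / ny
  list(x = g$x + jx, y = g$y + jy)
}

id_ranges_from <- function(pl) {
  types <- cell_type_order()
  rng <- list()
  for (tp in types) {
    ids <- pl$id[pl$cell_type == tp]
    rng[[tp]] <- if (length(ids)) c(min(ids), max(ids)) else c(NA_integer_, NA_integer_)
  }
  rng
}

#' Id range of a cell type in a placement
#' @param p A placement.
#' @param cell_type Type name.
#' @return Integer vector \code{c(first, last)} of global ids (NA if empty).
#' @export
id_range <- function(p, cell_type) {
  rng <- attr(p, "id_ranges")
  if (is.null(rng[[cell_type]])) stop("unknown cell type: ", cell_type, call. = FALSE)
  rng[[cell_type]]
}

#' Select cells of a type within a planar radius
#'
#' Returns global ids of cells of \code{cell_type} whose (x, y) Euclidean
#' distance to \code{center_xy} is at most \code{radius}, in ascending id
#' order. Used e.g. to pick the mossy fibers receiving a focal burst.
#'
#' @param p A placement.
#' @param cell_type Type name.
#' @param center_xy Numeric length-2, um.
#' @param radius Radius in um, >= 0.
#' @return Integer vector of global ids.
#' @export
select_sources_in_radius <- function(p, cell_type, center_xy, radius) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (!cell_type %in% cell_type_order()) {
    stop("unknown cell type: ", cell_type, call. = FALSE)
  }
  sub <- p[p$cell_type == cell_type, ]
  d2 <- (sub$x - center_xy[1])^2 + (sub$y - center_xy[2])^2
  sort(sub$id[!is.na(d2) & d2 <= radius^2])
}

#' Write / read a placement as CSV
#'
#' Tabular text interchange: columns \code{cell_type,id,x,y,z} with 0-based
#' per-type ids, so placements generated by other scaffold implementations
#' can be injected.
#'
#' @param p A placement.
#' @param path File path.
#' @return \code{write_placement} returns \code{path} invisibly;
#'   \code{read_placement} returns a placement (volume inferred from
#'   coordinate extents unless given).
#' @export
write_placement <- function(p, path) {
  df <- data.frame(cell_type = p$cell_type, id = p$local_id,
                   x = p$x, y = p$y, z = p$z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_placement
#' @param volume Optional [volume_spec()]; if NULL a bounding volume is
#'   inferred (placement-dependent; prefer passing the true spec).
#' @export
read_placement <- function(path, volume = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("placement file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df <- df[order(match(df$cell_type, cell_type_order()), df$id), ]
  pl <- tibble::tibble(cell_type = df$cell_type, local_id = as.integer(df$id),
                       x = df$x, y = df$y, z = df$z)
  pl$id <- seq_len(nrow(pl))
  pl <- pl[, c("cell_type", "local_id", "id", "x", "y", "z")]
  if (is.null(volume)) {
    volume <- volume_spec(
      x_extent = max(pl$x, na.rm = TRUE),
      y_extent = max(pl$y, na.rm = TRUE)
    )
  }
  structure(pl, volume = volume, id_ranges = id_ranges_from(pl),
            class = c("placement", class(pl)))
}
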