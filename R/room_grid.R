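#' Room occupancy grids
#'
#' A `room_grid` discretises a square virtual room into an
#' `n_cells_side` x `n_cells_side` grid of cells of edge `cell_m` metres
#' and records which cells are accessible (not occluded by furniture).
#' The count of accessible cells, `k_accessible`, is the normalising
#' constant `k` of path roaming entropy.
#'
#' @param accessible logical (or 0/1) matrix; rows index y (south to
#'   north), columns index x (west to east).
#' @param room_id identifier for the room.
#' @param cell_m cell edge length in metres.
#' @param room_label optional human-readable label.
#'
#' @return An object of class `room_grid`: a list with fields
#'   `room_id`, `room_label`, `side_m`, `cell_m`, `n_cells_side`,
#'   `accessible` (logical matrix) and `k_accessible`.
#' @export
room_grid <- function(accessible, room_id = "room", cell_m = 0.5,
                      room_label = room_id) {
  accessible <- as.matrix(accessible)
  if (nrow(accessible) != ncol(accessible)) {
    stop("accessibility mask must be square, got ", nrow(accessible), " x ",
         ncol(accessible))
  }
  if (is.numeric(accessible)) {
    if (!all(accessible %in% c(0, 1))) stop("mask entries must be 0 or 1")
    accessible <- accessible == 1
  }
  if (!is.logical(accessible) || anyNA(accessible)) {
    stop("mask must be logical or 0/1 without missing values")
  }
  k <- sum(accessible)
  if (k < 1) stop("room has no accessible cells")
  structure(
    list(
      room_id = as.character(room_id),
      room_label = as.character(room_label),
      side_m = ncol(accessible) * cell_m,
      cell_m = cell_m,
      n_cells_side = ncol(accessible),
      accessible = accessible,
      k_accessible = k
    ),
    class = "room_grid"
  )
}

#' @export
print.room_grid <- function(x, ...) {
  cat(sprintf("<room_grid '%s'> %.1f m x %.1f m, %d x %d cells of %.2f m, %d/%d accessible\n",
              x$room_id, x$side_m, x$side_m, x$n_cells_side, x$n_cells_side,
              x$cell_m, x$k_accessible, x$n_cells_side^2))
  invisible(x)
}

# cell index of the entry: middle of the south wall (row 1)
entry_cell <- function(n_cells_side) {
  c(row = 1L, col = as.integer(ceiling(n_cells_side / 2)))
}

# 4-connectivity check over TRUE cells via flood fill from `start` (row, col)
mask_connected <- function(mask, start) {
  if (!mask[start[1], start[2]]) return(FALSE)
  n <- nrow(mask)
  seen <- matrix(FALSE, n, ncol(mask))
  stack <- matrix(start, ncol = 2)
  seen[start[1], start[2]] <- TRUE
  while (nrow(stack) > 0) {
    cur <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      r <- cur[1] + d[1]; co <- cur[2] + d[2]
      if (r >= 1 && r <= n && co >= 1 && co <= ncol(mask) &&
          mask[r, co] && !seen[r, co]) {
        seen[r, co] <- TRUE
        stack <- rbind(stack, c(r, co))
      }
    }
  }
  all(seen[mask])
}

#' Generate a room with furniture-like occlusions
#'
#' Inaccessible cells are built from randomly placed rectangles
#' ("furniture blobs"), rejection-sampled so that the accessible region
#' stays 4-connected and the entry cell (middle of the south wall)
#' remains free. The realised occluded fraction tracks
#' `occlusion_fraction` up to blob-size rounding.
#'
#' @param seed integer seed controlling blob placement.
#' @param occlusion_fraction target fraction of occluded cells, in
#'   `[0, 0.6]`.
#' @param n_cells_side grid side length in cells (default 32).
#' @param cell_m cell edge in metres (default 0.5).
#' @param room_id,room_label identifiers passed to [room_grid()].
#' @param max_tries connectivity rejection-sampling budget.
#'
#' @return A [room_grid()].
#' @export
generate_room <- function(seed, occlusion_fraction = 0.25, n_cells_side = 32L,
                          cell_m = 0.5, room_id = "room", room_label = room_id,
                          max_tries = 50L) {
  if (occlusion_fraction < 0 || occlusion_fraction > 0.6) {
    stop("occlusion_fraction must be in [0, 0.6], got ", occlusion_fraction)
  }
  n <- as.integer(n_cells_side)
  target <- round(occlusion_fraction * n^2)
  ent <- entry_cell(n)
  for (try in seq_len(max_tries)) {
    rng <- local_rng(seed + 7919L * (try - 1L))
    mask <- matrix(TRUE, n, n)
    if (target > 0) {
      guard <- 0L
      while (sum(!mask) < target && guard < 400L) {
        guard <- guard + 1L
        w <- sample(1:5, 1)
        h <- sample(1:5, 1)
        # shrink the last blob rather than overshooting the target badly
        if (sum(!mask) + w * h > target + ceiling(w * h / 2)) next
        r0 <- sample(1:(n - h + 1), 1)
        c0 <- sample(1:(n - w + 1), 1)
        rows <- r0:(r0 + h - 1); cols <- c0:(c0 + w - 1)
        if (ent[1] %in% rows && ent[2] %in% cols) next
        mask[rows, cols] <- FALSE
      }
    }
    restore_rng(rng)
    if (mask[ent[1], ent[2]] && mask_connected(mask, ent)) {
      return(room_grid(mask, room_id = room_id, cell_m = cell_m,
                       room_label = room_label))
    }
  }
  stop("could not generate a connected room at occlusion_fraction = ",
       occlusion_fraction, " after ", max_tries,
       " attempts; lower the occlusion fraction")
}

# Scoped RNG helpers: run seeded draws without disturbing the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Read / write plain-text room masks
#'
#' Masks are whitespace-separated 0/1 grids, one row of the room per
#' line (row 1 = south wall). Ragged rows and non-binary tokens are
#' rejected.
#'
#' @param path file path.
#' @param room_id,cell_m,room_label passed to [room_grid()].
#' @return [read_mask()] returns a [room_grid()]; [write_mask()] returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, room_id = basename_noext(path), cell_m = 0.5,
                      room_label = room_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty mask file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  widths <- lengths(toks)
  if (length(unique(widths)) != 1) {
    stop("ragged mask rows in ", path, ": widths ",
         paste(unique(widths), collapse = ", "))
  }
  flat <- unlist(toks)
  if (!all(flat %in% c("0", "1"))) {
    bad <- unique(flat[!flat %in% c("0", "1")])
    stop("non-binary mask tokens in ", path, ": ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  m <- matrix(as.integer(flat), nrow = length(lines), byrow = TRUE)
  room_grid(m, room_id = room_id, cell_m = cell_m, room_label = room_label)
}

#' @rdname read_mask
#' @param room a [room_grid()].
#' @export
write_mask <- function(room, path) {
  stopifnot(inherits(room, "room_grid"))
  lines <- apply(room$accessible * 1L, 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

basename_noext <- function(path) sub("\\.[^.]*$", "", basename(path))
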