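# Reading and writing: calibrated TIFF volume series, 16-bit label TIFFs,
# Cell Tracking Challenge track files, CSV lineage tables.

INT16_MAX <- 65535

# TIFF samples are stored in [0, 1]; intensities are rescaled by an explicit
# factor kept in the YAML sidecar. Integer-valued series use 16-bit samples
# (lossless); everything else uses 32-bit float samples.
write_tiff_pages <- function(arr, path, bits, scale = INT16_MAX) {
  d <- dim(arr)
  pages <- lapply(seq_len(d[1]), function(z) {
    m <- arr[z, , , drop = TRUE]
    dim(m) <- d[2:3]
    storage.mode(m) <- "double"
    m / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  reduce = FALSE, compression = "none")
}

read_tiff_pages <- function(path, bits, scale = INT16_MAX) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) {
    m <- pages[[z]] * scale
    arr[z, , ] <- if (bits == 16) round(m) else m
  }
  arr
}

series_scale <- function(frames) {
  mx <- max(vapply(frames, max, 1), 1)
  integral <- all(vapply(frames, function(f) all(f == round(f)), TRUE))
  if (integral && mx <= INT16_MAX) list(bits = 16L, scale = INT16_MAX)
  else list(bits = 32L, scale = mx)
}

#' Write a volume series to disk
#'
#' Layout `"ZYX-sequence"`: one multi-page TIFF per frame (16-bit samples for
#' integer-valued series, 32-bit float otherwise, scaled via the sidecar)
#' (`frame_0000.tif`, pages = z slices) plus a `series.yaml` with the
#' calibration. Layout `"TZYX"`: a single multi-page TIFF with `T * Z` pages
#' and the same YAML sidecar (`<file>.yaml`).
#'
#' @param series a [volume_series()].
#' @param path output directory (`ZYX-sequence`) or `.tif` file (`TZYX`).
#' @param layout `"ZYX-sequence"` or `"TZYX"`.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(series, path, layout = c("ZYX-sequence", "TZYX")) {
  layout <- match.arg(layout)
  d <- dim(series$frames[[1]])
  enc <- series_scale(series$frames)
  meta <- list(layout = layout, frames = n_frames(series),
               shape_zyx = as.integer(d),
               voxel_size_um = series$voxel_size_um,
               frame_interval_s = series$frame_interval_s,
               time_origin_hpf = series$time_origin_hpf,
               bits = enc$bits, intensity_scale = enc$scale)
  if (layout == "ZYX-sequence") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (t in seq_len(n_frames(series)) - 1L)
      write_tiff_pages(frame_volume(series, t),
                       file.path(path, sprintf("frame_%04d.tif", t)),
                       enc$bits, enc$scale)
    yaml::write_yaml(meta, file.path(path, "series.yaml"))
  } else {
    stacked <- array(0, c(n_frames(series) * d[1], d[2], d[3]))
    for (t in seq_len(n_frames(series)) - 1L)
      stacked[t * d[1] + seq_len(d[1]), , ] <- frame_volume(series, t)
    write_tiff_pages(stacked, path, enc$bits, enc$scale)
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a volume series
#'
#' Counterpart of [write_volume_series()]. Calibration must be present in the
#' YAML sidecar or supplied via `voxel_size_um`/`frame_interval_s`; a missing
#' calibration is an error (isotropy is never assumed silently).
#'
#' @param path directory (`ZYX-sequence`) or `.tif` file (`TZYX`).
#' @param layout axis-order tag.
#' @param voxel_size_um,frame_interval_s calibration overrides.
#' @return a [volume_series()].
#' @export
read_volume_series <- function(path, layout = c("ZYX-sequence", "TZYX"),
                               voxel_size_um = NULL, frame_interval_s = NULL) {
  layout <- match.arg(layout)
  meta_path <- if (layout == "ZYX-sequence") file.path(path, "series.yaml")
  else paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  voxel_size_um <- voxel_size_um %||% meta$voxel_size_um
  frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
  if (is.null(voxel_size_um) || is.null(frame_interval_s))
    abort("calibration (voxel_size_um, frame_interval_s) is missing; supply it explicitly")
  bits <- meta$bits %||% 32L
  scale <- meta$intensity_scale %||% 1
  if (layout == "ZYX-sequence") {
    files <- sort(list.files(path, pattern = "^frame_\\d+\\.tif$",
                             full.names = TRUE))
    if (length(files) == 0) abort("no frame_*.tif files found")
    frames <- lapply(files, read_tiff_pages, bits = bits, scale = scale)
  } else {
    stacked <- read_tiff_pages(path, bits, scale)
    nz <- meta$shape_zyx[1] %||% abort("TZYX layout requires shape metadata")
    nt <- dim(stacked)[1] / nz
    if (nt != round(nt)) abort("page count is not a multiple of the stated Z size")
    frames <- lapply(seq_len(nt) - 1L, function(t)
      stacked[t * nz + seq_len(nz), , , drop = FALSE])
  }
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    abort("frames have inconsistent shapes")
  volume_series(frames, voxel_size_um, frame_interval_s,
                time_origin_hpf = meta$time_origin_hpf)
}

#' Write / read a 16-bit label series
#'
#' One 16-bit TIFF per frame (`mask_0000.tif`, CTC-style) plus calibration
#' YAML. Values above 65535 are rejected.
#'
#' @param labels a [label_series()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_label_series <- function(labels, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(n_frames(labels)) - 1L) {
    L <- frame_volume(labels, t)
    if (max(L) > INT16_MAX) abort("labels exceed 16-bit range")
    write_tiff_pages(L, file.path(path, sprintf("mask_%04d.tif", t)), 16)
  }
  yaml::write_yaml(list(voxel_size_um = labels$voxel_size_um,
                        frame_interval_s = labels$frame_interval_s),
                   file.path(path, "labels.yaml"))
  invisible(path)
}

#' @rdname write_label_series
#' @param voxel_size_um,frame_interval_s calibration overrides.
#' @export
read_label_series <- function(path, voxel_size_um = NULL,
                              frame_interval_s = NULL) {
  meta_path <- file.path(path, "labels.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  voxel_size_um <- voxel_size_um %||% meta$voxel_size_um
  frame_interval_s <- frame_interval_s %||% meta$frame_interval_s %||% 60
  if (is.null(voxel_size_um))
    abort("label calibration (voxel_size_um) is missing; supply it explicitly")
  files <- sort(list.files(path, pattern = "^mask_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) == 0) abort("no mask_*.tif files found")
  frames <- lapply(files, function(f) {
    a <- read_tiff_pages(f, 16)
    storage.mode(a) <- "integer"
    a
  })
  label_series(frames, voxel_size_um, frame_interval_s)
}

#' Export a lineage forest in Cell Tracking Challenge format
#'
#' Writes `res_track.txt` with one line `L B E P` per track (track label,
#' 0-based inclusive begin and end frames, parent track label or 0) and, when
#' a label series is supplied, 16-bit per-frame label TIFFs whose values are
#' the track labels. The text output is byte-stable for a given forest.
#'
#' @param forest a `lineage_forest`.
#' @param out_dir output directory.
#' @param labels optional [label_series()] whose values are the forest's node
#'   ids; re-labelled to track labels on export.
#' @return the track table, invisibly.
#' @export
export_tracks_ctc <- function(forest, out_dir, labels = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- forest$nodes
  # track labels: contiguous positive integers ordered by (start frame, id)
  tr <- n |> group_by(.data$track_id) |>
    summarise(b = min(.data$frame), e = max(.data$frame),
              first_id = .data$id[which.min(.data$frame)])
  tr <- tr[order(tr$b, tr$first_id), ]
  tr$L <- seq_len(nrow(tr))
  lab_of_track <- setNames(tr$L, tr$track_id)
  first_nodes <- n$id[match(tr$track_id, n$track_id)]
  # parent track: track of the parent node of the track's first node
  firsts <- n[n$id %in% tr$first_id, ]
  firsts <- firsts[match(tr$first_id, firsts$id), ]
  par_node <- firsts$parent_id
  P <- ifelse(is.na(par_node), 0L,
              lab_of_track[as.character(n$track_id[match(par_node, n$id)])])
  lines <- sprintf("%d %d %d %d", tr$L, tr$b, tr$e, as.integer(P))
  writeLines(lines, file.path(out_dir, "res_track.txt"))
  if (!is.null(labels)) {
    node_track_label <- setNames(lab_of_track[as.character(n$track_id)], n$id)
    frames <- lapply(seq_len(n_frames(labels)) - 1L, function(t) {
      L <- frame_volume(labels, t)
      out <- array(0L, dim(L))
      pos <- L > 0L
      vals <- node_track_label[as.character(L[pos])]
      if (any(is.na(vals)))
        vals[is.na(vals)] <- 0L
      out[pos] <- as.integer(vals)
      # a track label must be unique within the frame by construction;
      # collisions mean two same-frame nodes share a track
      out
    })
    for (t in sort(unique(n$frame))) {
      tid <- n$track_id[n$frame == t & !n$interpolated]
      if (anyDuplicated(tid))
        abort("label collision: two same-frame nodes share a track")
    }
    write_label_series(label_series(frames, labels$voxel_size_um,
                                    labels$frame_interval_s),
                       out_dir)
  }
  invisible(tibble(L = tr$L, B = tr$b, E = tr$e, P = as.integer(P)))
}

#' Parse a Cell Tracking Challenge track file into a forest
#'
#' Reconstructs a `lineage_forest` from `res_track.txt` (and node geometry
#' from the label TIFFs when present; otherwise nodes carry NA positions).
#'
#' @param dir directory containing `res_track.txt` (and optional masks).
#' @return a `lineage_forest`.
#' @export
parse_tracks_ctc <- function(dir) {
  tt <- read.table(file.path(dir, "res_track.txt"),
                   col.names = c("L", "B", "E", "P"))
  has_masks <- length(list.files(dir, pattern = "^mask_\\d+\\.tif$")) > 0
  labs <- if (has_masks) read_label_series(dir) else NULL
  nodes <- list()
  nid <- 0L
  first_node <- integer(nrow(tt))
  last_node <- integer(nrow(tt))
  for (k in seq_len(nrow(tt))) {
    fr <- tt$B[k]:tt$E[k]
    ids <- nid + seq_along(fr)
    nid <- nid + length(fr)
    first_node[k] <- ids[1]; last_node[k] <- ids[length(fr)]
    pos <- matrix(NA_real_, length(fr), 3)
    vol <- rep(NA_real_, length(fr))
    if (!is.null(labs)) {
      for (i in seq_along(fr)) {
        L <- frame_volume(labs, fr[i])
        vox <- which(L == tt$L[k])
        if (length(vox)) {
          um <- voxel_to_um(unlin_index(vox, dim(L)), labs$voxel_size_um)
          pos[i, ] <- colMeans(um)
          vol[i] <- length(vox) * prod(labs$voxel_size_um)
        }
      }
    }
    nodes[[k]] <- tibble(id = ids, frame = fr, z = pos[, 1], y = pos[, 2],
                         x = pos[, 3], volume_um3 = vol,
                         parent_id = c(NA_integer_, ids[-length(ids)]),
                         track_id = tt$L[k], interpolated = FALSE)
  }
  nodes <- bind_rows(nodes)
  for (k in seq_len(nrow(tt))) {
    if (tt$P[k] > 0) {
      pk <- match(tt$P[k], tt$L)
      nodes$parent_id[match(first_node[k], nodes$id)] <- last_node[pk]
    }
  }
  lineage_forest(nodes)
}

#' Export / import the lineage table
#'
#' Flat CSV with one row per node: id, frame, z, y, x, parent_id, track_id,
#' division_flag. The round trip preserves graph topology exactly.
#'
#' @param forest a `lineage_forest`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
export_lineage_table <- function(forest, path) {
  n <- forest$nodes
  divs <- division_nodes(forest)
  out <- tibble(id = n$id, frame = n$frame, z = n$z, y = n$y, x = n$x,
                parent_id = n$parent_id, track_id = n$track_id,
                division_flag = n$id %in% divs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_lineage_table
#' @export
parse_lineage_table <- function(path) {
  tt <- utils::read.csv(path)
  if (nrow(tt) == 0) {
    return(lineage_forest(tibble(id = integer(), frame = integer(),
                                 z = numeric(), y = numeric(), x = numeric(),
                                 volume_um3 = numeric(), parent_id = integer(),
                                 track_id = integer(),
                                 interpolated = logical())))
  }
  lineage_forest(tibble(id = tt$id, frame = tt$frame, z = tt$z, y = tt$y,
                        x = tt$x, volume_um3 = NA_real_,
                        parent_id = tt$parent_id, track_id = tt$track_id,
                        interpolated = FALSE))
}
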