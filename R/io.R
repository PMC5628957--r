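# Tabular trajectory I/O.  The on-disk format is a plain CSV with header
# `frame,id,x_mm,y_mm` (one row per fish per frame, frames contiguous per
# id), plus an optional JSON/YAML sidecar holding fps, body length, arena,
# cover disc and patch list.  The loader rejects gaps rather than
# interpolating: tracks are expected to be complete.

#' Write a group trajectory to CSV (+ JSON sidecar)
#'
#' @param gt A [group_trajectory()].
#' @param path Output CSV path.  A sidecar `<path>.json` with fps, body
#'   length and geometry is written alongside unless `sidecar = FALSE`.
#' @param sidecar Logical; write the metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(gt, path, sidecar = TRUE) {
  stopifnot(inherits(gt, "group_trajectory"))
  nf <- n_frames(gt)
  tabs <- lapply(gt$trajectories, function(tr) {
    data.frame(frame = seq_len(nf) - 1L, id = tr$id,
               x_mm = tr$x, y_mm = tr$y)
  })
  tab <- do.call(rbind, tabs)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(
      fps = gt$trajectories[[1L]]$fps,
      body_length_mm = gt$trajectories[[1L]]$body_length,
      arena = gt$arena, cover = gt$cover,
      patches = lapply(gt$patches, unclass))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a group trajectory from CSV (+ sidecar)
#'
#' Rejects files with missing frames, duplicate (frame, id) rows or
#' non-numeric coordinates, naming the offending row.
#'
#' @param path CSV path with header `frame,id,x_mm,y_mm`.
#' @param sidecar Optional path to a JSON or YAML metadata sidecar; defaults
#'   to `<path>.json` / `<path>.yaml` when present.
#' @param fps,body_length Fallback metadata when no sidecar is found.
#' @return A [group_trajectory()].
#' @export
read_trajectories <- function(path, sidecar = NULL, fps = 24,
                              body_length = 40.6) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "id", "x_mm", "y_mm")
  if (!all(need %in% names(tab))) {
    stop("format-error: header must contain frame,id,x_mm,y_mm")
  }
  for (col in c("x_mm", "y_mm", "frame")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("format-error: non-numeric %s at row %d", col, bad))
    }
    tab[[col]] <- v
  }
  key <- paste(tab$frame, tab$id)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf("format-error: duplicate (frame,id) at row %d", bad))
  }
  meta <- read_sidecar(path, sidecar)
  if (!is.null(meta$fps)) fps <- meta$fps
  if (!is.null(meta$body_length_mm)) body_length <- meta$body_length_mm

  trajs <- lapply(split(tab, tab$id), function(sub) {
    sub <- sub[order(sub$frame), , drop = FALSE]
    fr <- sub$frame
    if (any(diff(fr) != 1)) {
      gap <- which(diff(fr) != 1)[1L]
      stop(sprintf("format-error: missing frame after %d for id '%s'",
                   as.integer(fr[gap]), sub$id[1L]))
    }
    trajectory(sub$x_mm, sub$y_mm, id = sub$id[1L], fps = fps,
               body_length = body_length)
  })
  patches <- NULL
  if (!is.null(meta$patches) && length(meta$patches)) {
    plist <- meta$patches
    if (is.data.frame(plist)) {
      plist <- lapply(seq_len(nrow(plist)), function(r) {
        as.list(plist[r, , drop = FALSE])
      })
    }
    patches <- lapply(plist, function(p) {
      p[vapply(p, function(v) all(is.na(unlist(v))), logical(1))] <- NULL
      food_patch(center = unlist(p$center),
                 half_width = unlist(p$half_width),
                 radius = unlist(p$radius),
                 items_initial = if (is.null(p$items_initial)) 5L
                                 else unlist(p$items_initial))
    })
  }
  group_trajectory(trajs, arena = meta$arena, cover = meta$cover,
                   patches = patches)
}

read_sidecar <- function(path, sidecar) {
  if (is.null(sidecar)) {
    for (cand in paste0(path, c(".json", ".yaml", ".yml"))) {
      if (file.exists(cand)) {
        sidecar <- cand
        break
      }
    }
  }
  if (is.null(sidecar)) return(list())
  if (grepl("\\.ya?ml$", sidecar)) {
    yaml::read_yaml(sidecar)
  } else {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
}
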