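fmt_num <- function(x) {
  # >= 9 significant digits, locale-independent, deterministic
  sprintf("%.12g", x)
}

#' Write / read a detection table as CSV
#'
#' Column header `id,frame,x,y,area,orientation`; floats are serialised with
#' 12 significant digits so the round trip is lossless to well past the stated
#' 9-digit precision. Extra columns (e.g. a `ctc_label` track column written
#' by [write_fixture()]) are preserved.
#'
#' @param detections detection table.
#' @param path file path.
#' @return `write_detections` returns `path` invisibly; `read_detections`
#'   returns the validated detection table.
#' @export
write_detections <- function(detections, path) {
  detections <- cbind(as_detections(detections),
                      detections[setdiff(names(detections),
                                         c("id", "frame", "x", "y", "area",
                                           "orientation"))])
  out <- detections
  for (col in c("x", "y", "area", "orientation")) out[[col]] <- fmt_num(out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- read.csv(path)
  extra <- setdiff(names(df), c("id", "frame", "x", "y", "area", "orientation"))
  cbind(as_detections(df), df[extra])
}

#' Convert a lineage forest to Cell Tracking Challenge track records
#'
#' The CTC `res_track.txt` / `man_track.txt` dialect: whitespace-separated
#' lines `L B E P` where `L` is the track label, `B`/`E` its first and last
#' frame and `P` the parent track label (0 for none). A track is a maximal
#' migration chain; a division ends the mother track and starts two daughter
#' tracks carrying its label as `P`. Labels are assigned in order of (begin
#' frame, smallest detection id) for determinism.
#'
#' @param forest a `lineage_forest`.
#' @return data.frame with columns `L`, `B`, `E`, `P` and attribute `labels`,
#'   a data.frame mapping every detection `id` to its track `label` (needed to
#'   reconstruct edges from point detections, which carry no mask labels).
#' @export
forest_to_ctc <- function(forest) {
  det <- forest$detections
  ids <- det$id
  frame_of <- setNames(det$frame, ids)
  parent_of <- setNames(forest$parent_id, ids)
  nchild <- children_counts(forest)
  # track starts: roots, and children of divisions
  div_child <- !is.na(forest$parent_id) &
    nchild[as.character(forest$parent_id)] == 2
  starts <- ids[is.na(forest$parent_id) | div_child]
  starts <- starts[order(frame_of[as.character(starts)], starts)]
  child_of <- split(ids[!is.na(forest$parent_id)],
                    forest$parent_id[!is.na(forest$parent_id)])
  tracks <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    chain <- starts[i]
    cur <- starts[i]
    repeat {
      ch <- child_of[[as.character(cur)]]
      if (is.null(ch) || length(ch) != 1) break
      cur <- ch
      chain <- c(chain, cur)
    }
    tracks[[i]] <- chain
  }
  label_of <- integer(0)
  for (i in seq_along(tracks)) {
    label_of[as.character(tracks[[i]])] <- i
  }
  rec <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    chain <- tracks[[i]]
    first <- chain[1]
    par_det <- parent_of[[as.character(first)]]
    data.frame(L = i,
               B = unname(frame_of[[as.character(first)]]),
               E = unname(frame_of[[as.character(chain[length(chain)])]]),
               P = if (is.na(par_det)) 0L
                   else unname(label_of[[as.character(par_det)]]))
  }))
  if (is.null(rec)) {
    rec <- data.frame(L = integer(0), B = integer(0), E = integer(0),
                      P = integer(0))
  }
  attr(rec, "labels") <- data.frame(id = as.integer(names(label_of)),
                                    label = unname(label_of))
  rec
}

#' Rebuild a lineage forest from CTC track records
#'
#' Inverse of [forest_to_ctc()]. Because detections are points (no label
#' masks), the detection table must carry a `ctc_label` column assigning each
#' detection to its track.
#'
#' @param records data.frame with columns `L`, `B`, `E`, `P`.
#' @param detections detection table with a `ctc_label` column.
#' @return a `lineage_forest`.
#' @export
ctc_to_forest <- function(records, detections) {
  if (!"ctc_label" %in% names(detections)) {
    uat_abort("detections need a ctc_label column to pair with CTC records",
              "uat_error_ctc")
  }
  labels <- detections$ctc_label
  det <- as_detections(detections)
  if (any(records$B > records$E) || any(records$L <= 0)) {
    uat_abort("invalid CTC record (B > E or non-positive label)",
              "uat_error_ctc")
  }
  ends <- setNames(records$E, records$L)
  bad_parent <- records$P != 0 &
    (!(records$P %in% records$L) | ends[as.character(records$P)] >= records$B)
  if (any(bad_parent)) {
    uat_abort("CTC parent must be an existing track ending before the child begins",
              "uat_error_ctc")
  }
  edges <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    sel <- which(labels == r$L)
    sel <- sel[order(det$frame[sel])]
    if (length(sel) == 0) next
    if (anyDuplicated(det$frame[sel])) {
      uat_abort(sprintf("track label %d reused within a frame", r$L),
                "uat_error_ctc")
    }
    if (length(sel) > 1) {
      edges[[length(edges) + 1]] <- data.frame(parent = det$id[sel[-length(sel)]],
                                               child = det$id[sel[-1]])
    }
    if (r$P != 0) {
      psel <- which(labels == r$P)
      pend <- psel[which.max(det$frame[psel])]
      edges[[length(edges) + 1]] <- data.frame(parent = det$id[pend],
                                               child = det$id[sel[1]])
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else NULL
  build_forest(edges, det)
}

#' Write / read CTC track records
#' @param records data.frame with columns `L`, `B`, `E`, `P`.
#' @param path file path (conventionally `res_track.txt` or `man_track.txt`).
#' @return `write_ctc` returns `path` invisibly; `read_ctc` the records.
#' @export
write_ctc <- function(records, path) {
  write.table(records[c("L", "B", "E", "P")], path, row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_ctc
#' @export
read_ctc <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(L = integer(0), B = integer(0), E = integer(0),
                      P = integer(0)))
  }
  df <- read.table(path, col.names = c("L", "B", "E", "P"))
  df
}

#' Export forest edges (optionally with posterior marginals) as JSON
#'
#' @param forest a `lineage_forest`.
#' @param path file path.
#' @param marginals optional data.frame from [edge_marginals()]; matched edges
#'   gain a `fraction` field.
#' @return `path`, invisibly.
#' @export
write_edges_json <- function(forest, path, marginals = NULL) {
  edges <- forest_edges(forest)
  names(edges) <- c("parent_id", "child_id")
  if (!is.null(marginals) && nrow(edges) > 0) {
    key <- paste(edges$parent_id, edges$child_id)
    mkey <- paste(marginals$parent, marginals$child)
    edges$fraction <- marginals$fraction[match(key, mkey)]
  }
  jsonlite::write_json(edges, path, dataframe = "rows", digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write / read a simulated dataset fixture
#'
#' A fixture directory holds `detections.csv` (with a `ctc_label` column),
#' `man_track.txt` (the ground-truth lineage in CTC format) and `meta.json`
#' (interval, flags, unresolved-gap count). The round trip is lossless and,
#' for a fixed `(params, seed)` pair, regeneration is bitwise stable.
#'
#' @param dataset a `uat_dataset`.
#' @param dir directory (created if missing).
#' @return `write_fixture` returns `dir` invisibly; `read_fixture` the
#'   reconstructed `uat_dataset` (with `params = NULL`).
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- forest_to_ctc(dataset$truth)
  labels <- attr(rec, "labels")
  det <- dataset$detections
  det$ctc_label <- labels$label[match(det$id, labels$id)]
  det$ctc_label[is.na(det$ctc_label)] <- 0L
  write_detections(det, file.path(dir, "detections.csv"))
  write_ctc(rec, file.path(dir, "man_track.txt"))
  jsonlite::write_json(list(dt = dataset$dt, capped = dataset$capped,
                            unresolved = dataset$unresolved),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  det <- read_detections(file.path(dir, "detections.csv"))
  rec <- read_ctc(file.path(dir, "man_track.txt"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  truth <- ctc_to_forest(rec, det)
  structure(list(detections = as_detections(det), truth = truth,
                 dt = meta$dt, params = NULL,
                 capped = isTRUE(meta$capped),
                 unresolved = as.integer(meta$unresolved)),
            class = "uat_dataset")
}
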