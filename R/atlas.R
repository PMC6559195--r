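# Hierarchical atlas operations: ontology ingestion and validation,
# parental-label aggregation, hemisphere splitting, ROI overlap reports and
# subject incidence maps. Label volumes carry the ontology ids directly as
# voxel codes (0 = background).

#' Create / validate an atlas ontology table
#'
#' An ontology is a forest of labelled regions: every row has a unique
#' positive `id`, an `acronym`, a `name` and a `parent_id` (NA for roots).
#' Validation checks id uniqueness, that every parent exists, and that the
#' parent links are acyclic.
#'
#' @param df data frame with columns `id`, `acronym`, `name`, `parent_id`.
#' @return The validated data frame with class `ontology_table`.
#' @export
ontology_table <- function(df) {
  need <- c("id", "acronym", "name", "parent_id")
  if (!all(need %in% names(df))) {
    stop("ontology needs columns: ", paste(need, collapse = ", "))
  }
  df$id <- as.integer(df$id)
  df$parent_id <- suppressWarnings(as.integer(df$parent_id))
  if (any(is.na(df$id)) || any(df$id <= 0)) stop("ontology ids must be positive integers")
  if (anyDuplicated(df$id)) stop("duplicate ontology ids")
  known <- df$parent_id[!is.na(df$parent_id)]
  if (!all(known %in% df$id)) {
    stop("parent_id values missing from ontology: ",
         paste(setdiff(known, df$id), collapse = ", "))
  }
  # cycle check by walking every node to a root
  parent <- setNames(df$parent_id, df$id)
  for (id in df$id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle detected in ontology at id ", cur)
      seen <- c(seen, cur)
      cur <- parent[[as.character(cur)]]
    }
  }
  class(df) <- c("ontology_table", "data.frame")
  df
}

#' Read an atlas ontology from CSV
#'
#' The CSV must have a header with columns `id`, `acronym`, `name`,
#' `parent_id` (empty or NA `parent_id` marks a root).
#'
#' @param path CSV file path.
#' @return An [ontology_table()].
#' @export
read_ontology <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ontology_table(df)
}

# Ancestor chain of `id` (excluding id itself), child -> root order.
ontology_ancestors <- function(ont, id) {
  parent <- setNames(ont$parent_id, ont$id)
  out <- integer(0)
  cur <- parent[[as.character(id)]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- parent[[as.character(cur)]]
  }
  out
}

#' Create a label volume
#'
#' @param vol an [mri_volume()] (or integer array) of non-negative integer
#'   region codes, 0 = background. Codes are ontology ids.
#' @param voxel_size,orientation passed to [mri_volume()] when `vol` is a
#'   plain array.
#' @param hemisphere_offset integer added to right-hemisphere codes by
#'   [split_hemispheres()]; stored for round-tripping.
#' @return An `mri_volume` with `modality = "label"` and a
#'   `hemisphere_offset` attribute.
#' @export
label_volume <- function(vol, voxel_size = c(1, 1, 1), orientation = "RAS",
                         hemisphere_offset = NULL) {
  if (!inherits(vol, "mri_volume")) {
    vol <- mri_volume(vol, voxel_size, orientation, modality = "label")
  }
  if (any(vol$data < 0) || any(vol$data != round(vol$data))) {
    stop("label volume must hold non-negative integer codes")
  }
  vol$modality <- "label"
  attr(vol, "hemisphere_offset") <- hemisphere_offset
  vol
}

#' Aggregate a label volume to parental regions
#'
#' Remaps every voxel label to its nearest ancestor contained in
#' `parent_set`, walking child -> parent through the ontology (a label
#' already in `parent_set` maps to itself). This is how a fine parcellation
#' of >1,000 regions is coarsened to a tractable parental atlas. Labels
#' with no ancestor in `parent_set` map to background and are reported in
#' the `orphans` attribute.
#'
#' @param lab a label `mri_volume` (codes are ontology ids).
#' @param ont an [ontology_table()].
#' @param parent_set integer vector of ontology ids to aggregate to.
#' @return The aggregated label volume; attributes `orphans` (codes dropped
#'   to background) and `mapping` (named vector old -> new).
#' @export
aggregate_to_parents <- function(lab, ont, parent_set) {
  stopifnot(inherits(lab, "mri_volume"), inherits(ont, "ontology_table"))
  parent_set <- as.integer(parent_set)
  if (length(parent_set) == 0) stop("'parent_set' is empty")
  if (!all(parent_set %in% ont$id)) {
    stop("parent_set ids not in ontology: ",
         paste(setdiff(parent_set, ont$id), collapse = ", "))
  }
  codes <- sort(unique(as.vector(lab$data)))
  codes <- codes[codes != 0]
  if (!all(codes %in% ont$id)) {
    stop("label codes not in ontology: ", paste(setdiff(codes, ont$id), collapse = ", "))
  }
  mapping <- integer(length(codes))
  names(mapping) <- codes
  for (i in seq_along(codes)) {
    chain <- c(codes[i], ontology_ancestors(ont, codes[i]))
    hit <- chain[chain %in% parent_set]
    mapping[i] <- if (length(hit)) hit[1] else 0L
  }
  lut <- integer(max(codes) + 1L)       # lut[code + 1] = new code
  lut[codes + 1L] <- mapping
  out <- lab
  out$data <- array(lut[as.vector(lab$data) + 1L], dim(lab$data))
  attr(out, "orphans") <- as.integer(names(mapping)[mapping == 0L])
  attr(out, "mapping") <- mapping
  out
}

#' Split a label volume into hemispheres
#'
#' Adds `hemisphere_offset` to the codes of all non-background voxels on
#' the right side of the midline (`x > midline` in RAS, where +x points to
#' the subject's right), so left and right instances of each region can be
#' compared. Per base label, left + right voxel counts equal the original
#' count.
#'
#' @param lab a label `mri_volume`.
#' @param midline_index 0-based x index of the midline; voxels with
#'   x-index strictly greater get the offset. Default: centre column.
#' @param hemisphere_offset integer offset; must exceed every existing code.
#' @return The split label volume (offset stored as attribute).
#' @export
split_hemispheres <- function(lab, midline_index = NULL, hemisphere_offset = 20000L) {
  stopifnot(inherits(lab, "mri_volume"))
  d <- dim(lab$data)
  if (is.null(midline_index)) midline_index <- (d[1] - 1) / 2
  if (midline_index < 0 || midline_index > d[1] - 1) stop("midline outside x extent")
  mx <- max(lab$data)
  if (mx >= hemisphere_offset) {
    stop("hemisphere offset ", hemisphere_offset,
         " collides with existing codes (max ", mx, ")")
  }
  right <- array(rep((seq_len(d[1]) - 1) > midline_index, prod(d[2:3])), d)
  out <- lab
  out$data <- lab$data + hemisphere_offset * (right & lab$data != 0)
  attr(out, "hemisphere_offset") <- as.integer(hemisphere_offset)
  out
}

#' Merge a hemisphere-split label volume
#'
#' Inverse of [split_hemispheres()]: removes the offset from
#' right-hemisphere codes.
#'
#' @param lab a split label `mri_volume`.
#' @param hemisphere_offset offset used for the split (defaults to the
#'   stored attribute).
#' @return The merged label volume.
#' @export
merge_hemispheres <- function(lab, hemisphere_offset = attr(lab, "hemisphere_offset")) {
  stopifnot(inherits(lab, "mri_volume"), !is.null(hemisphere_offset))
  out <- lab
  out$data <- lab$data - hemisphere_offset * (lab$data >= hemisphere_offset)
  attr(out, "hemisphere_offset") <- NULL
  out
}

#' Report atlas regions overlapping a ROI
#'
#' For every atlas region intersecting a binary ROI (e.g. a lesion mask),
#' reports the overlap voxel count, the fraction of the region covered and
#' the fraction of the ROI it accounts for, sorted by overlap size.
#'
#' @param roi binary `mri_volume` (or array).
#' @param lab a label `mri_volume` of the same shape.
#' @param ont an [ontology_table()] supplying acronyms/names.
#' @return Data frame (label_id, acronym, name, voxels_in_roi,
#'   fraction_of_region, fraction_of_roi), with the background fraction of
#'   the ROI as attribute `background_fraction`.
#' @export
region_overlap_report <- function(roi, lab, ont) {
  stopifnot(inherits(lab, "mri_volume"), inherits(ont, "ontology_table"))
  r <- if (inherits(roi, "mri_volume")) roi$data != 0 else as.array(roi) != 0
  if (!identical(dim(r), dim(lab$data))) stop("ROI and label shapes differ")
  n_roi <- sum(r)
  if (n_roi == 0) stop("empty ROI")
  codes_in <- as.vector(lab$data)[as.vector(r)]
  tab <- table(codes_in[codes_in != 0])
  ids <- as.integer(names(tab))
  counts <- as.integer(tab)
  region_tot <- vapply(ids, function(id) sum(lab$data == id), numeric(1))
  base_id <- ids
  off <- attr(lab, "hemisphere_offset")
  if (!is.null(off)) base_id <- ifelse(ids >= off, ids - off, ids)
  meta <- ont[match(base_id, ont$id), c("acronym", "name")]
  out <- data.frame(
    label_id = ids,
    acronym = meta$acronym,
    name = meta$name,
    voxels_in_roi = counts,
    fraction_of_region = counts / region_tot,
    fraction_of_roi = counts / n_roi,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$voxels_in_roi), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "background_fraction") <- 1 - sum(out$fraction_of_roi)
  out
}

#' Voxelwise incidence map over subjects
#'
#' Sums binary masks (e.g. lesion segmentations of N mice) voxelwise; the
#' value at a voxel is the number of subjects whose mask covers it.
#'
#' @param masks non-empty list of binary `mri_volume`s (or arrays) of equal
#'   shape.
#' @return An `mri_volume` of counts in `[0, N]`.
#' @export
incidence_map <- function(masks) {
  if (length(masks) == 0) stop("need at least one mask")
  arrs <- lapply(masks, function(m) if (inherits(m, "mri_volume")) m$data else as.array(m))
  d <- dim(arrs[[1]])
  for (a in arrs) {
    if (!identical(dim(a), d)) stop("mask shapes differ")
    if (!all(a %in% c(0, 1))) stop("masks must be binary (0/1)")
  }
  s <- Reduce(`+`, arrs)
  tmpl <- masks[[1]]
  if (inherits(tmpl, "mri_volume")) {
    as_volume_like(s, tmpl, modality = "label")
  } else {
    mri_volume(s, c(1, 1, 1), "RAS", modality = "label")
  }
}
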