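#' Compartment roles recognized by the phantom pipeline
#'
#' @return Character vector of valid compartment roles.
#' @export
compartment_roles <- function() {
  c("liver", "spleen", "tumour", "cortex-L", "cortex-R",
    "medulla-L", "medulla-R", "body", "other")
}

validate_organ_table <- function(organ_table) {
  if (!is.data.frame(organ_table) || nrow(organ_table) == 0L)
    stop("organ_table must be a non-empty data frame")
  if (!all(c("id", "name", "role") %in% names(organ_table)))
    stop("organ_table must have columns id, name, role")
  if (any(organ_table$id == 0L))
    stop("label 0 is reserved for 'outside' and may not appear in organ_table")
  if (anyDuplicated(organ_table$id))
    stop("duplicate ids in organ_table")
  bad <- setdiff(organ_table$role, compartment_roles())
  if (length(bad))
    stop("unknown compartment role(s): ", paste(bad, collapse = ", "))
  organ_table
}

#' Construct a labelled voxel phantom
#'
#' A voxel phantom is a 3-D integer label volume (0 = outside) with voxel
#' spacing in mm and an organ table mapping each label id to an organ name
#' and a compartment role. The world coordinate of voxel index `(i, j, k)`
#' (0-based) is `((i + 0.5) sx, (j + 0.5) sy, (k + 0.5) sz)` mm, i.e. voxel
#' centers sit half a voxel in from the grid origin.
#'
#' @param label_data 3-D integer array, or a vector together with `shape`.
#' @param spacing voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @param organ_table data frame with columns `id`, `name`, `role`
#'   (role from [compartment_roles()]).
#' @param shape integer triple; required when `label_data` is a plain
#'   vector, checked against its length.
#' @return An object of class `voxel_phantom` with elements `labels`,
#'   `spacing`, `organ_table`.
#' @export
load_voxel_phantom <- function(label_data, spacing, organ_table, shape = NULL) {
  if (is.null(dim(label_data))) {
    if (is.null(shape))
      stop("label_data has no dimensions and no shape was declared")
    if (length(label_data) != prod(shape))
      stop("shape mismatch: ", length(label_data), " values for declared shape ",
           paste(shape, collapse = "x"))
    dim(label_data) <- shape
  } else if (!is.null(shape) && !identical(as.integer(dim(label_data)),
                                           as.integer(shape))) {
    stop("shape mismatch: data is ", paste(dim(label_data), collapse = "x"),
         ", declared ", paste(shape, collapse = "x"))
  }
  if (length(dim(label_data)) != 3L)
    stop("label volume must be three-dimensional")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 1 or 3 strictly positive values (mm)")
  organ_table <- validate_organ_table(organ_table)
  storage.mode(label_data) <- "integer"
  present <- sort(unique(as.vector(label_data)))
  present <- present[present != 0L]
  unknown <- setdiff(present, organ_table$id)
  if (length(unknown))
    stop("label(s) absent from organ_table: ", paste(unknown, collapse = ", "))
  structure(list(labels = label_data, spacing = as.numeric(spacing),
                 organ_table = organ_table),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("Voxel phantom:", paste(d, collapse = " x "), "voxels at",
      paste(format(x$spacing), collapse = " x "), "mm\n")
  v <- phantom_volumes(x)
  if (nrow(v)) print(v, row.names = FALSE)
  invisible(x)
}

#' Per-organ voxel counts and volumes
#'
#' @param phantom a `voxel_phantom`.
#' @return Data frame with `id`, `name`, `role`, `voxels`, `volume_mL`
#'   (voxel count times voxel volume).
#' @export
phantom_volumes <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  tab <- tabulate(phantom$labels, nbins = max(phantom$organ_table$id))
  vox_mL <- prod(phantom$spacing) / 1000
  ot <- phantom$organ_table
  data.frame(id = ot$id, name = ot$name, role = ot$role,
             voxels = tab[ot$id],
             volume_mL = tab[ot$id] * vox_mL,
             stringsAsFactors = FALSE)
}

#' Binary mask of one organ
#'
#' @param phantom a `voxel_phantom`.
#' @param label organ id, or an organ role/name string.
#' @return Logical 3-D array.
#' @export
organ_mask <- function(phantom, label) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  id <- resolve_label(phantom, label)
  phantom$labels == id
}

resolve_label <- function(phantom, label) {
  ot <- phantom$organ_table
  if (is.numeric(label)) {
    if (!label %in% ot$id) stop("unknown label id: ", label)
    return(as.integer(label))
  }
  hit <- which(ot$role == label | ot$name == label)
  if (length(hit) != 1L)
    stop("label '", label, "' matches ", length(hit), " organ-table entries")
  ot$id[hit]
}

#' Merge label regions
#'
#' Relabels voxels according to a mapping of old ids to new ids (for
#' example, combining the renal pelvis into the medulla to obtain a
#' two-compartment kidney). The total number of nonzero voxels never
#' changes; merged ids are dropped from the organ table.
#'
#' @param phantom a `voxel_phantom`.
#' @param mapping named integer vector: `names` are old ids, values are the
#'   ids they merge into. Both sides must exist in the organ table.
#' @return The relabelled `voxel_phantom`.
#' @export
merge_labels <- function(phantom, mapping) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  old <- as.integer(names(mapping))
  new <- as.integer(mapping)
  if (length(old) == 0L) return(phantom)
  ot <- phantom$organ_table
  missing_old <- setdiff(old, ot$id)
  if (length(missing_old))
    stop("mapping references id(s) absent from organ_table: ",
         paste(missing_old, collapse = ", "))
  missing_new <- setdiff(new, ot$id)
  if (length(missing_new))
    stop("mapping targets id(s) absent from organ_table: ",
         paste(missing_new, collapse = ", "))
  lut <- seq_len(max(ot$id))
  lut[old] <- new
  lab <- phantom$labels
  nz <- lab != 0L
  lab[nz] <- lut[lab[nz]]
  drop <- setdiff(old, new)
  phantom$labels <- lab
  phantom$organ_table <- ot[!ot$id %in% drop, , drop = FALSE]
  phantom
}

# 6-connected component labelling of a logical 3-D mask.
# Returns an integer array: 0 outside the mask, 1..n_components inside,
# component 1 being the largest (ties broken by discovery order).
label_components6 <- function(mask) {
  d <- dim(mask)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  offs <- c(-1L, 1L, -pd[1], pd[1], -pd[1] * pd[2], pd[1] * pd[2])
  comp <- integer(prod(pd))
  unvisited <- pm
  sizes <- integer(0)
  cur <- 0L
  seeds <- which(pm)
  for (seed in seeds) {
    if (!unvisited[seed]) next
    cur <- cur + 1L
    comp[seed] <- cur
    unvisited[seed] <- FALSE
    frontier <- seed
    size <- 1L
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[unvisited[nb]]
      if (length(nb)) {
        comp[nb] <- cur
        unvisited[nb] <- FALSE
        size <- size + length(nb)
      }
      frontier <- nb
    }
    sizes[cur] <- size
  }
  dim(comp) <- pd
  comp <- comp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
  # renumber so that component 1 is the largest
  if (length(sizes) > 1L) {
    ord <- order(sizes, decreasing = TRUE)
    ranks <- integer(length(sizes))
    ranks[ord] <- seq_along(sizes)
    nz <- comp != 0L
    comp[nz] <- ranks[comp[nz]]
    sizes <- sizes[ord]
  }
  attr(comp, "sizes") <- sizes
  comp
}

#' Clean a label region to a single connected component
#'
#' Enforces that the region of `label` is a single 6-connected component
#' with no small interior cavities of other labels: voxels of `label`
#' outside its largest connected component are reassigned to `reassign_to`,
#' and enclosed cavities (connected components of other labels completely
#' surrounded by the region) smaller than `cavity_threshold` voxels are
#' absorbed into `label`. This automates the manual label tidying needed
#' before surface extraction.
#'
#' @param phantom a `voxel_phantom`.
#' @param label id, role or name of the region to clean.
#' @param reassign_to id, role or name receiving detached voxels.
#' @param cavity_threshold absorb cavities strictly smaller than this many
#'   voxels (default 27, i.e. up to a 3x3x3 pocket).
#' @return The cleaned `voxel_phantom`, with attribute `cleanup_log`, a list
#'   with `moved_detached` and `absorbed_cavity` voxel counts.
#' @export
clean_label_region <- function(phantom, label, reassign_to,
                               cavity_threshold = 27L) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  id <- resolve_label(phantom, label)
  to <- resolve_label(phantom, reassign_to)
  lab <- phantom$labels
  mask <- lab == id
  if (!any(mask)) stop("region of label ", id, " is empty")

  # work in the region's bounding box, padded one voxel
  w <- which(mask)
  co <- arrayInd(w, dim(mask))
  lo <- pmax(apply(co, 2, min) - 1L, 1L)
  hi <- pmin(apply(co, 2, max) + 1L, dim(mask))
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_lab <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  comp <- label_components6(sub)
  detached <- comp > 1L
  n_detached <- sum(detached)
  sub_lab[detached] <- to
  main <- comp == 1L

  # cavities: components of the complement that do not reach the sub-volume
  # border (the border component is the outside)
  compl_comp <- label_components6(!main)
  border_ids <- unique(c(compl_comp[1, , ], compl_comp[dim(compl_comp)[1], , ],
                         compl_comp[, 1, ], compl_comp[, dim(compl_comp)[2], ],
                         compl_comp[, , 1], compl_comp[, , dim(compl_comp)[3]]))
  border_ids <- border_ids[border_ids != 0L]
  sizes <- attr(compl_comp, "sizes")
  cavity_ids <- setdiff(seq_along(sizes), border_ids)
  cavity_ids <- cavity_ids[sizes[cavity_ids] < cavity_threshold]
  n_cavity <- 0L
  if (length(cavity_ids)) {
    cav <- compl_comp %in% cavity_ids
    dim(cav) <- dim(compl_comp)
    n_cavity <- sum(cav)
    sub_lab[cav] <- id
  }

  lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub_lab
  phantom$labels <- lab
  attr(phantom, "cleanup_log") <- list(moved_detached = n_detached,
                                       absorbed_cavity = n_cavity)
  phantom
}

#' Write / read a voxel phantom as raw binary plus YAML sidecar
#'
#' The label volume is stored as little-endian unsigned integers (8-bit by
#' default, 16-bit when labels exceed 255), x fastest, with a `.yaml`
#' sidecar recording shape, spacing, data type and the organ table.
#'
#' @param phantom a `voxel_phantom`.
#' @param prefix path prefix; writes `<prefix>.raw` and `<prefix>.yaml`.
#' @return `write_voxel_phantom()`: the prefix, invisibly;
#'   `read_voxel_phantom()`: the reconstructed `voxel_phantom`.
#' @export
write_voxel_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  lab <- phantom$labels
  size <- if (max(lab) > 255L) 2L else 1L
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.integer(lab), con, size = size, endian = "little")
  meta <- list(
    shape = as.integer(dim(lab)),
    spacing_mm = phantom$spacing,
    dtype = if (size == 1L) "uint8" else "uint16",
    byte_order = "little",
    organs = lapply(seq_len(nrow(phantom$organ_table)), function(i)
      as.list(phantom$organ_table[i, c("id", "name", "role")]))
  )
  yaml::write_yaml(meta, paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_voxel_phantom
#' @export
read_voxel_phantom <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  shape <- as.integer(meta$shape)
  size <- switch(meta$dtype, uint8 = 1L, uint16 = 2L,
                 stop("unsupported dtype: ", meta$dtype))
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "integer", n = prod(shape), size = size,
                  signed = FALSE, endian = meta$byte_order)
  if (length(vals) != prod(shape))
    stop("raw file truncated: read ", length(vals), " of ", prod(shape),
         " voxels")
  ot <- do.call(rbind, lapply(meta$organs, function(o)
    data.frame(id = as.integer(o$id), name = o$name, role = o$role,
               stringsAsFactors = FALSE)))
  load_voxel_phantom(vals, as.numeric(meta$spacing_mm), ot, shape = shape)
}
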