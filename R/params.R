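# Hierarchical parameter handling. Every tunable of the pipeline lives in one
# default tree; user settings (from a YAML/JSON file or an in-code list)
# override defaults, and nested routines receive their sub-tree via
# resolve_hierarchy(). Keys use dotted paths, e.g.
# segmsurf.getminima.nucleus.thrs.th reaches the iterative-threshold
# multiplier of the nucleus segmentation that generates watershed markers.

# Defaults for the nucleus/cytoplasm segmentation thread (segment_nuclei).
segmct_defaults <- function() {
  list(
    method = "thrs",               # 'thrs' (iterative) or 'adth' (adaptive)
    thrs = list(th = 1.0),         # multiplier of the Otsu threshold
    adth = list(adth = 0.20, filtrad = 20),  # offset (fraction of range), window radius (vox)
    split = 1,                     # split fused objects via distance transform
    splitth = 1.0,                 # h-maxima depth (um); smaller => more splitting
    splitplane = "auto",           # 'auto' => round(nz / 3), else 1-based plane
    smoothim = list(method = "eed", planewise = 1,
                    iterations = 10, time_step = 0.15, sigma = 1, rho = 3,
                    lambda = 0.05,
                    gaussian_radius = 4, gaussian_sd = 1,
                    dirced_line_length = 9, dirced_n_orientations = 8)
  )
}

#' Default parameter tree
#'
#' Returns the full hierarchical parameter set of the pipeline with every key
#' at its documented default. Users override entries through a parameter file
#' ([read_parameter_file()]) or a nested list passed to the main routines;
#' direct arguments have the highest priority, then the file, then these
#' defaults.
#'
#' @return A named nested list (class `memseg_params`).
#' @export
#' @examples
#' p <- default_parameters()
#' p$segmsurf$getminima$method
default_parameters <- function() {
  prm <- list(
    segmentation = "segmsurf",     # batch-level choice: 'segmsurf' or 'segmct'
    nchannels = 2,                 # channels per stack file (surface, nucleus)
    segmplane = 1,                 # copy this plane's labels down to plane 1
    h = c(0.5, 0.5, 1.5),          # fallback voxel size (um) when no sidecar/tags
    illum = 0,                     # top-hat illumination correction on/off
    illumdiameter = 25,            # structuring-disk diameter (um)
    smoothim = list(method = "dirced", planewise = 1,
                    iterations = 10, time_step = 0.15, sigma = 1, rho = 3,
                    lambda = 0.05,
                    gaussian_radius = 4, gaussian_sd = 1,
                    dirced_line_length = 9, dirced_n_orientations = 8),
    subtractsd = 1.0,              # Gaussian sd (vox) for nucleus-channel subtraction
    segmsurf = list(
      filterridges = 1,
      ridge = list(scale = 2, weight = 0.5),
      getminima = list(
        method = "automated",      # 'automated', 'nucleus' or 'manual'
        level = "default",         # 'strong' => marker plane of maximal intensity
        adapt_a = 0.02,            # relative lift of the local-mean threshold
        nucleus = segmct_defaults()
      ),
      classifycells = list(
        method = "threshold",      # 'threshold' or 'minimacell'
        propname = "all",
        intincell = 10,            # max interior / background intensity ratio
        intborder = 2,             # min boundary / background intensity ratio
        convexarea = 0.4,
        convexperim = 0.4,
        meanintbck = NA_real_      # manual background mean (NA => from background region)
      )
    ),
    segmct = segmct_defaults()
  )
  structure(prm, class = "memseg_params")
}

# Flatten a nested list to dotted-path -> value.
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v)) out <- c(out, flatten_params(v, path))
    else out[[path]] <- v
  }
  out
}

# Rebuild a nested list from dotted paths.
unflatten_params <- function(flat) {
  out <- list()
  for (path in names(flat)) {
    keys <- strsplit(path, ".", fixed = TRUE)[[1]]
    out <- assign_path(out, keys, flat[[path]])
  }
  out
}

assign_path <- function(tree, keys, value) {
  if (length(keys) == 1L) { tree[[keys]] <- value; return(tree) }
  sub <- tree[[keys[1]]]
  if (!is.list(sub)) sub <- list()
  tree[[keys[1]]] <- assign_path(sub, keys[-1], value)
  tree
}

# Validate user overrides against the default tree and merge. Unknown dotted
# paths and type mismatches are rejected with the offending path.
merge_params <- function(defaults, user) {
  if (is.null(user) || length(user) == 0L) return(defaults)
  def_flat <- flatten_params(defaults)
  usr_flat <- flatten_params(user)
  for (path in names(usr_flat)) {
    if (!path %in% names(def_flat))
      stop("unknown parameter: '", path, "'", call. = FALSE)
    dv <- def_flat[[path]]; uv <- usr_flat[[path]]
    if (is.numeric(dv) && !is.numeric(uv)) {
      # accept 0/1-style flags written as logicals
      if (is.logical(uv)) uv <- as.numeric(uv)
      else stop("parameter '", path, "' must be numeric", call. = FALSE)
    }
    if (is.character(dv) && !is.character(uv) && !all(is.na(uv)))
      stop("parameter '", path, "' must be a string", call. = FALSE)
    def_flat[[path]] <- uv
  }
  structure(unflatten_params(def_flat), class = "memseg_params")
}

#' Read a parameter file
#'
#' Reads a YAML or JSON parameter file, with either nested sections or dotted
#' keys (`segmsurf.getminima.method: nucleus`), validates every entry against
#' the default tree and returns the merged parameter set. An empty file yields
#' the full default set. Booleans may be written `0`/`1`, `true`/`false`.
#'
#' @param path File path; extension `.json` selects JSON, anything else YAML.
#' @return A `memseg_params` nested list.
#' @export
read_parameter_file <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  # dotted top-level keys are expanded to nested form before merging
  flat <- list()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.list(v)) flat <- c(flat, flatten_params(setNames(list(v), nm)))
    else flat[[nm]] <- v
  }
  merge_params(default_parameters(), unflatten_params(flat))
}

#' Extract the parameter sub-tree a nested routine receives
#'
#' The parameter hierarchy mirrors the call chain: the surface pipeline calls
#' the marker detector, which may call the nucleus segmentation. A key such as
#' `segmsurf.getminima.nucleus.thrs.th`, resolved at prefix
#' `segmsurf.getminima.nucleus`, becomes `thrs.th` at the nucleus-segmentation
#' level. An empty prefix returns the input unchanged. Resolution composes:
#' resolving at `a` then at `b` equals resolving at `a.b`.
#'
#' @param prm A nested parameter list.
#' @param prefix Dotted path of the sub-tree, or `""`.
#' @return The sub-tree (an empty list when the prefix is absent).
#' @export
resolve_hierarchy <- function(prm, prefix) {
  if (!nzchar(prefix)) return(prm)
  keys <- strsplit(prefix, ".", fixed = TRUE)[[1]]
  for (k in keys) {
    if (!is.list(prm) || is.null(prm[[k]])) return(list())
    prm <- prm[[k]]
  }
  prm
}

# Resolved segmct-level parameters for the nucleus marker path.
nucleus_segmct_params <- function(prm) {
  sub <- resolve_hierarchy(prm, "segmsurf.getminima.nucleus")
  merge_params(structure(segmct_defaults(), class = "memseg_params"), sub)
}
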