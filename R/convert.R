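#' Convert an R-serialised C-alpha coordinate cache to ensembles
#'
#' Published trajectory subsets are sometimes deposited as `.RData` files
#' of C-alpha positions (e.g. per-replicate frame subsets for each
#' variant). This converter loads such a cache, validates its layout, and
#' returns [traj_ensemble()] objects (optionally also writing multi-model
#' PDB files, one per variant/replicate).
#'
#' Expected object layout (validated, never assumed silently): the file
#' contains one named list (or several top-level objects, one per
#' variant); each variant maps to replicates; each replicate is either
#' a `T x 3N` numeric matrix in xyz order `(x1, y1, z1, x2, ...)`, a
#' `T x N x 3` array, or a list of `N x 3` matrices. Optional attributes
#' `chain` and `resno` (length N) supply atom metadata; otherwise atoms
#' are numbered 1..N on chain `"B"`. Any other shape is a hard error
#' naming the offending object so the mapping can be fixed against the
#' real file rather than guessed.
#'
#' @param path `.RData` file path.
#' @param out_dir optional directory; when given, writes
#'   `out_dir/{variant}/{temperature}/{replicate}.pdb` plus
#'   `manifest.json`.
#' @param frame_interval frame interval in ps recorded on the ensembles.
#' @param temperature temperature label in K for all ensembles in this
#'   cache (caches at other temperatures are separate files).
#' @return named list: variant -> list of [traj_ensemble()]s.
#' @export
convert_calpha_cache <- function(path, out_dir = NULL, frame_interval = 2,
                                 temperature = 300) {
  if (!file.exists(path)) stop("cache file not found: ", path)
  env <- new.env(parent = emptyenv())
  loaded <- load(path, envir = env)
  if (!length(loaded)) stop("cache contains no objects")
  objs <- mget(loaded, envir = env)
  # a single top-level named list is the variant map; otherwise each
  # top-level object is one variant
  if (length(objs) == 1L && is.list(objs[[1]]) && !is.data.frame(objs[[1]])) {
    if (is.null(names(objs[[1]])) || any(!nzchar(names(objs[[1]]))))
      stop("cache layout mismatch: variant entries must be named")
    objs <- objs[[1]]
  }
  if (is.null(names(objs)) || any(!nzchar(names(objs))))
    stop("cache layout mismatch: variant entries must be named")

  # one replicate is a T x 3N matrix, a T x N x 3 array, or a list of
  # N x 3 per-frame matrices; a variant entry is a replicate or a list of
  # replicates (3-column matrices are taken as per-frame lists)
  is_frame_list <- function(x)
    is.list(x) && length(x) && all(vapply(x, function(e)
      is.matrix(e) && ncol(e) == 3L, logical(1)))
  result <- list()
  for (vn in names(objs)) {
    v <- objs[[vn]]
    reps <- if (is.matrix(v) || (is.array(v) && length(dim(v)) == 3L)) list(v)
            else if (is.list(v) && is_frame_list(v)) list(v)
            else if (is.list(v)) v
            else list(v)
    ens_list <- list()
    for (ri in seq_along(reps)) {
      frames <- coerce_cache_frames(reps[[ri]], vn, ri)
      n <- dim(frames)[2]
      chain <- attr(reps[[ri]], "chain")
      resno <- attr(reps[[ri]], "resno")
      if (is.null(chain)) chain <- rep("B", n)
      if (is.null(resno)) resno <- seq_len(n)
      if (length(chain) == 1L) chain <- rep(chain, n)
      if (length(chain) != n || length(resno) != n)
        stop(sprintf("cache layout mismatch: '%s' replicate %d metadata length != %d atoms",
                     vn, ri, n))
      atoms <- data.frame(atom_index = seq_len(n), atom_name = "CA",
                          residue_number = as.integer(resno),
                          residue_name = "ALA", chain_id = chain,
                          stringsAsFactors = FALSE)
      ens_list[[ri]] <- traj_ensemble(atoms, frames, frame_interval, vn, ri,
                                      temperature)
    }
    result[[vn]] <- ens_list
  }

  if (!is.null(out_dir)) {
    manifest <- list(source = path, temperature = temperature, variants = list())
    for (vn in names(result)) {
      tdir <- file.path(out_dir, vn, as.character(temperature))
      dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
      files <- character(0)
      for (ri in seq_along(result[[vn]])) {
        f <- file.path(tdir, sprintf("%d.pdb", ri))
        write_ensemble(result[[vn]][[ri]], f)
        files <- c(files, f)
      }
      manifest$variants[[vn]] <- files
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

coerce_cache_frames <- function(x, variant, replicate) {
  where <- sprintf("'%s' replicate %d", variant, replicate)
  if (is.list(x) && !is.null(dim(x[[1]]))) {
    mats <- lapply(x, as.matrix)
    if (any(vapply(mats, ncol, 0L) != 3L))
      stop("cache layout mismatch: ", where, " frame matrices are not N x 3")
    n <- nrow(mats[[1]])
    if (any(vapply(mats, nrow, 0L) != n))
      stop("cache layout mismatch: ", where, " frames differ in atom count")
    frames <- array(0, dim = c(length(mats), n, 3L))
    for (t in seq_along(mats)) frames[t, , ] <- mats[[t]]
    return(frames)
  }
  if (is.array(x) && !is.matrix(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] != 3L)
      stop("cache layout mismatch: ", where, " array is not T x N x 3")
    return(array(as.numeric(x), dim = dim(x)))  # drop stray attributes
  }
  if (is.matrix(x)) {
    if (ncol(x) %% 3L != 0L)
      stop("cache layout mismatch: ", where,
           " matrix has ", ncol(x), " columns (not a multiple of 3)")
    n <- ncol(x) %/% 3L
    return(aperm(array(t(x), dim = c(3L, n, nrow(x))), c(3L, 2L, 1L)))
  }
  stop("cache layout mismatch: ", where,
       " is neither a T x 3N matrix, a T x N x 3 array, nor a list of N x 3 matrices")
}
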