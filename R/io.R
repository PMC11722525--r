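# K-space container I/O. The on-disk layout mirrors the hierarchical
# groups of the usual raw-data containers (/data, /traj, /echoes, /meta)
# in a single self-describing file with an explicit format version, so
# trajectory and data can never separate.

.kspace_format_version <- "wfr2star-kspace-1"

#' Write a multi-echo k-space container to disk
#'
#' Lossless single-file serialization with groups `data`, `traj`,
#' `echoes`, `meta` and a format-version tag; round trips are bit-exact.
#'
#' @param y A [multi_echo_kspace()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_kspace <- function(y, path) {
  stopifnot(inherits(y, "multi_echo_kspace"))
  obj <- list(format_version = .kspace_format_version,
              data = y$data,
              traj = unclass(y$traj),
              echoes = unclass(y$echoes),
              meta = y$meta)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a multi-echo k-space container from disk
#'
#' Validates the format version and the presence and consistency of all
#' groups before reconstructing the in-memory object.
#'
#' @param path File written by [write_kspace()].
#' @return A [multi_echo_kspace()] object.
#' @export
read_kspace <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version))
    stop("k-space container format error: missing format_version tag")
  if (!identical(obj$format_version, .kspace_format_version))
    stop(sprintf("unsupported k-space container version '%s' (expected '%s')",
                 obj$format_version, .kspace_format_version))
  for (grp in c("data", "traj", "echoes", "meta"))
    if (is.null(obj[[grp]]))
      stop(sprintf("k-space container format error: missing group '%s'", grp))
  traj <- structure(obj$traj, class = "radial_trajectory")
  echoes <- structure(obj$echoes, class = "echo_train")
  multi_echo_kspace(obj$data, traj, echoes, obj$meta)
}

#' Principal-component coil compression
#'
#' Compresses the coil dimension to `n_virtual` virtual coils via the SVD
#' of the coil-by-sample data matrix (principal component analysis along
#' the coil dimension), reporting the retained energy fraction.
#'
#' @param y A [multi_echo_kspace()] object.
#' @param n_virtual Number of virtual coils, `1 <= n_virtual <= n_coils`.
#' @return A [multi_echo_kspace()] with compressed coil dimension; the
#'   retained energy fraction is stored in `meta$coil_compression_energy`.
#' @export
coil_compress <- function(y, n_virtual) {
  stopifnot(inherits(y, "multi_echo_kspace"))
  K <- dim(y$data)[1]
  n_virtual <- as.integer(n_virtual)
  if (n_virtual < 1L || n_virtual > K)
    stop("n_virtual must be between 1 and the number of coils")
  dm <- dim(y$data)
  X <- matrix(y$data, nrow = K)           # coils x everything
  sv <- svd(X, nu = K, nv = 0)
  U <- sv$u[, seq_len(n_virtual), drop = FALSE]
  Xc <- Conj(t(U)) %*% X
  energy <- sum(sv$d[seq_len(n_virtual)]^2) / sum(sv$d^2)
  meta <- y$meta
  meta$coil_compression_energy <- energy
  meta$n_physical_coils <- K
  multi_echo_kspace(array(Xc, dim = c(n_virtual, dm[2], dm[3], dm[4])),
                    y$traj, y$echoes, meta)
}

#' Write parameter maps as NIfTI volumes
#'
#' One file per map: water and fat as real/imaginary pairs, R2*, B0, and
#' the derived fat fraction in percent. The affine encodes the in-plane
#' voxel size `fov/n`.
#'
#' @param maps A [parameter_maps()] object (or a [recon_state()], whose
#'   maps are used).
#' @param path_prefix Path prefix; suffixes
#'   `_{water,fat}_{real,imag}.nii.gz`, `_r2star.nii.gz`, `_fb0.nii.gz`,
#'   `_fatfrac.nii.gz` are appended.
#' @param fov_mm Field of view in mm (sets the voxel size).
#' @return Character vector of the files written, invisibly.
#' @export
write_maps <- function(maps, path_prefix, fov_mm) {
  if (inherits(maps, "recon_state")) maps <- maps$maps
  stopifnot(inherits(maps, "parameter_maps"), fov_mm > 0)
  n <- nrow(maps$water)
  vox <- fov_mm / n
  wr <- function(img, suffix) {
    f <- paste0(path_prefix, suffix, ".nii.gz")
    nii <- RNifti::asNifti(img)
    RNifti::pixdim(nii) <- c(vox, vox)
    RNifti::writeNifti(nii, f)
    f
  }
  files <- c(
    wr(Re(maps$water), "_water_real"), wr(Im(maps$water), "_water_imag"),
    wr(Re(maps$fat), "_fat_real"), wr(Im(maps$fat), "_fat_imag"),
    wr(maps$r2star, "_r2star"), wr(maps$fb0, "_fb0"),
    wr(fat_fraction(maps), "_fatfrac")
  )
  invisible(files)
}

#' Read parameter maps written by [write_maps()]
#'
#' @param path_prefix Prefix used when writing.
#' @return A [parameter_maps()] object.
#' @export
read_maps <- function(path_prefix) {
  rd <- function(suffix) {
    img <- RNifti::readNifti(paste0(path_prefix, suffix, ".nii.gz"))
    matrix(as.vector(img), nrow = dim(img)[1])
  }
  parameter_maps(
    water = rd("_water_real") + 1i * rd("_water_imag"),
    fat = rd("_fat_real") + 1i * rd("_fat_imag"),
    r2star = rd("_r2star"),
    fb0 = rd("_fb0")
  )
}
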