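#' Skull fracture rule
#'
#' The skull is deemed fractured when strictly more than `fraction` of all
#' skull elements exceed (strictly) the ultimate strength of bone in peak
#' von Mises stress. The 4% default corresponds to the share of skull
#' elements spanning the full skull thickness.
#'
#' @param peak_vm per-skull-element peak von Mises stress (MPa).
#' @param strength ultimate strength of bone (MPa).
#' @param fraction fracture fraction threshold.
#' @return logical flag.
#' @export
skull_fractured <- function(peak_vm, strength = 92.72, fraction = 0.04) {
  if (length(peak_vm) == 0L) abort("no skull elements supplied.")
  if (any(peak_vm < 0)) abort("peak von Mises values must be >= 0.")
  mean(peak_vm > strength) > fraction
}

#' Map a binary voxel mask to mesh elements
#'
#' Step 1: select mesh nodes whose world coordinates fall inside a true
#' voxel (voxel-centre convention: node at world `x` lies in voxel
#' `floor(affine^-1 x + 0.5)`, 0-based). Step 2: return every gray-matter
#' element sharing at least one selected node.
#'
#' @param mesh a `head_mesh`.
#' @param dmn_mask logical 3D array with a 4x4 voxel-to-world transform as
#'   attribute `"affine"` (as produced by [binarize_dmn_template()]).
#' @param affine optional explicit affine overriding the attribute.
#' @return sorted integer vector of gray element ids.
#' @export
map_dmn_elements <- function(mesh, dmn_mask, affine = NULL) {
  stopifnot(inherits(mesh, "head_mesh"))
  affine <- affine %||% attr(dmn_mask, "affine")
  if (is.null(affine)) abort("mask must carry an `affine` attribute.")
  gray <- which(mesh$region == "gray")
  if (length(gray) == 0L) abort("mesh has no gray-matter elements.")
  dims <- dim(dmn_mask)

  inv <- solve(affine)
  vox <- t(inv %*% rbind(t(mesh$nodes), 1))[, 1:3, drop = FALSE]
  idx <- floor(vox + 0.5)   # 0-based voxel index per node
  inside <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
            idx[, 2] >= 0 & idx[, 2] < dims[2] &
            idx[, 3] >= 0 & idx[, 3] < dims[3]
  sel <- logical(nrow(mesh$nodes))
  ii <- which(inside)
  if (length(ii)) {
    flat <- idx[ii, 1] + dims[1] * (idx[ii, 2] + dims[2] * idx[ii, 3]) + 1
    sel[ii] <- as.logical(dmn_mask)[flat]
  }
  has_sel <- matrix(sel[mesh$tets[gray, , drop = FALSE]],
                    ncol = 4L)
  sort(gray[rowSums(has_sel) > 0])
}

#' DMN damage percentage from peak shear-energy-rate fields
#'
#' An element is damaged when its peak shear energy rate strictly exceeds
#' the criterion (default 1 MJ/m^3/s; the blast-calibrated 100 MJ/m^3/s is
#' available as the named preset `damage_threshold_presets()["blast"]`).
#'
#' @param peaks a `peak_fields` object, or a numeric vector of peak shear
#'   energy rates named/indexed by element id.
#' @param dmn_ids non-empty integer vector of DMN element ids.
#' @param threshold damage criterion (MJ/m^3/s).
#' @return object of class `damage_result`: list with `fractured` (NA when
#'   unknown), `dmn_element_ids`, `damaged_element_ids`, `damage_percent`.
#' @export
dmn_damage_percent <- function(peaks, dmn_ids, threshold = 1.0) {
  if (length(dmn_ids) == 0L) {
    abort("`dmn_ids` must be non-empty (damage percentage undefined).")
  }
  if (inherits(peaks, "peak_fields")) {
    ser <- rep(NA_real_, max(peaks$gray_ids))
    ser[peaks$gray_ids] <- peaks$gray_ser
  } else {
    ser <- as.numeric(peaks)
  }
  vals <- ser[dmn_ids]
  if (any(is.na(vals))) abort("peak field missing for some DMN elements.")
  damaged <- dmn_ids[vals > threshold]
  structure(
    list(fractured = NA, dmn_element_ids = dmn_ids,
         damaged_element_ids = damaged,
         damage_percent = 100 * length(damaged) / length(dmn_ids)),
    class = "damage_result"
  )
}

#' Named presets for the element damage criterion
#'
#' `impact` (1 MJ/m^3/s) is the value calibrated against the functional
#' criterion for blunt head impact; `blast` (100 MJ/m^3/s) is the earlier
#' blast-loading calibration, retained for reference.
#'
#' @return named numeric vector (MJ/m^3/s).
#' @export
damage_threshold_presets <- function() {
  c(impact = 1, blast = 100)
}

#' @export
print.damage_result <- function(x, ...) {
  cat(sprintf("<damage_result> %d / %d DMN elements damaged (%.2f%%)\n",
              length(x$damaged_element_ids), length(x$dmn_element_ids),
              x$damage_percent))
  invisible(x)
}
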