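#' Component registry
#'
#' The registry enumerates the unique color components contributed by the
#' seventeen supported spaces and fixes the column order of every pixel
#' feature matrix. The default ("printed") registry is the published 32-name
#' list, from `H_HSI` to `i3_i1i2i3`. Because the published optimal subset
#' also references `V_HSV`, which the printed list omits, an "extended"
#' variant appends `V_HSV` under its own identifier, and
#' [deduplicated_registry()] offers a formula-identity alternative that
#' rebuilds the list from all 51 planes by removing numerically identical
#' columns. The printed list and the deduplicated list are both exposed; no
#' claim is made that they coincide.
#'
#' @name component-registry
NULL

.PRINTED_32 <- data.frame(
  id = c("H_HSI", "S_HSI", "I_HSI",
         "L_LAB", "A_LAB", "B_LAB",
         "U_LUV", "V_LUV",
         "R_nRGB", "G_nRGB", "B_nRGB",
         "R_RGB", "G_RGB", "B_RGB",
         "S_TSL", "L_TSL",
         "X_XYZ", "Y_XYZ", "Z_XYZ",
         "Y_YCBCR", "CB_YCBCR", "CR_YCBCR",
         "CG_YCGCR", "CR_YCGCR",
         "E_YES", "S_YES",
         "Q_YIQ",
         "PB_YPBPR", "PR_YPBPR",
         "i1_i1i2i3", "i2_i1i2i3", "i3_i1i2i3"),
  space = c(rep("HSI", 3), rep("LAB", 3), rep("LUV", 2), rep("nRGB", 3),
            rep("RGB", 3), rep("TSL", 2), rep("XYZ", 3), rep("YCbCr", 3),
            rep("YCgCr", 2), rep("YES", 2), "YIQ", rep("YPbPr", 2),
            rep("i1i2i3", 3)),
  component = c("H", "S", "I", "L", "A", "B", "U", "V", "R", "G", "B",
                "R", "G", "B", "S", "L", "X", "Y", "Z", "Y", "CB", "CR",
                "CG", "CR", "E", "S", "Q", "PB", "PR", "i1", "i2", "i3"),
  stringsAsFactors = FALSE)

#' Build a component registry
#'
#' @param variant `"printed"` (default) for the published 32-component list,
#'   or `"extended"` to append `V_HSV` (referenced by the published optimal
#'   subset but absent from the printed list).
#' @return A `component_registry`: a data frame with columns `id`, `space`
#'   and `component`, in registry order.
#' @examples
#' registry_size(component_registry())  # 32
#' @export
component_registry <- function(variant = c("printed", "extended")) {
  variant <- match.arg(variant)
  reg <- .PRINTED_32
  if (variant == "extended")
    reg <- rbind(reg, data.frame(id = "V_HSV", space = "HSV",
                                 component = "V", stringsAsFactors = FALSE))
  structure(reg, class = c("component_registry", "data.frame"))
}

#' @rdname component_registry
#' @param registry A `component_registry`.
#' @export
registry_size <- function(registry) {
  check_registry(registry)
  nrow(registry)
}

check_registry <- function(registry) {
  if (!inherits(registry, "component_registry") &&
      !(is.data.frame(registry) &&
        all(c("id", "space", "component") %in% names(registry))))
    stopf("not a component registry")
  if (nrow(registry) < 1L) stopf("registry must be non-empty")
  if (anyDuplicated(registry$id)) stopf("registry identifiers must be unique")
  invisible(registry)
}

#' Formula-identity deduplicated registry
#'
#' Enumerates all 51 planes of the seventeen spaces and drops every plane
#' that is numerically identical (max abs difference below `tol` on a random
#' pixel sample) to an earlier one, keeping first occurrences in space order.
#' This is the reconstructible counterpart of the printed 32-name list.
#'
#' @param tol Numerical identity tolerance.
#' @param n_probe Number of random probe pixels.
#' @param seed Seed for the probe sample.
#' @return A `component_registry` of the surviving planes.
#' @export
deduplicated_registry <- function(tol = 1e-9, n_probe = 2048, seed = 1L) {
  rgb <- with_seed(seed, matrix(stats::runif(n_probe * 3), ncol = 3))
  ids <- character(0); spaces <- character(0); comps <- character(0)
  seen <- NULL
  for (sp in color_spaces()) {
    vals <- transform_rows(rgb, sp)
    for (j in seq_len(ncol(vals))) {
      v <- vals[, j]
      dup <- !is.null(seen) && any(apply(seen, 2, function(u) max(abs(u - v)) < tol))
      if (!dup) {
        seen <- cbind(seen, v)
        # printed-list naming style: uppercase suffix except the
        # conventionally mixed-case space names
        sfx <- if (sp %in% c("nRGB", "i1i2i3")) sp else toupper(sp)
        ids <- c(ids, paste0(colnames(vals)[j], "_", sfx))
        spaces <- c(spaces, sp)
        comps <- c(comps, colnames(vals)[j])
      }
    }
  }
  structure(data.frame(id = ids, space = spaces, component = comps,
                       stringsAsFactors = FALSE),
            class = c("component_registry", "data.frame"))
}

# Compute the registry's component columns for an n x 3 RGB matrix.
# Each space is transformed once; columns are picked in registry order.
registry_values <- function(rgb, registry = component_registry()) {
  check_registry(registry)
  cache <- list()
  out <- matrix(0, nrow(rgb), nrow(registry))
  for (i in seq_len(nrow(registry))) {
    sp <- registry$space[i]
    if (is.null(cache[[sp]])) cache[[sp]] <- transform_rows(rgb, sp)
    out[, i] <- cache[[sp]][, registry$component[i]]
  }
  colnames(out) <- registry$id
  out
}

#' Size of the k-subset combination space
#'
#' Number of distinct component subsets of size `k` drawn from the registry:
#' `choose(m, k)` for a registry of `m` components. With the default
#' 32-component registry and `k = 3` this is 4960.
#'
#' @param registry A `component_registry` (default: the printed 32-name list).
#' @param k Subset size, `0 <= k <= registry_size(registry)`.
#' @return The binomial coefficient as a double.
#' @examples
#' combination_space_size(k = 3)  # 4960
#' @export
combination_space_size <- function(registry = component_registry(), k) {
  m <- registry_size(registry)
  if (!is_count(k, min = 0) || k > m)
    stopf("k must be an integer in [0, %d]", m)
  choose(m, k)
}
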