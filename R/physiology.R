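#' Airway geometry of the human upper and lower respiratory tract
#'
#' Container for the geometric inputs from which the nasal epithelial lining
#' fluid (ELF) and mucosal tissue volumes and the per-segment
#' permeability-surface area (PS) products are derived.  Defaults are the
#' adult human values used throughout the package: nasal internal surface
#' area 0.0246 m^2, nasal ELF thickness 1e-6 m, nasal tissue thickness
#' 1.15e-4 m, bronchial (BB) and bronchiolar (bb) surface areas 0.75 m^2,
#' alveolar (AL) surface area 140 m^2.
#'
#' @param S_Nose nasal internal surface area, m^2.
#' @param H_Nose nasal ELF (mucus) thickness, m.
#' @param D_Nose nasal mucosal tissue thickness, m.
#' @param S_BB,S_bb,S_AL bronchial, bronchiolar and alveolar surface
#'   areas, m^2.
#' @return An object of class `nasal_geometry` (named list).
#' @examples
#' nasal_geometry()
#' @export
nasal_geometry <- function(S_Nose = 0.0246, H_Nose = 1e-6, D_Nose = 1.15e-4,
                           S_BB = 0.75, S_bb = 0.75, S_AL = 140) {
  g <- list(S_Nose = S_Nose, H_Nose = H_Nose, D_Nose = D_Nose,
            S_BB = S_BB, S_bb = S_bb, S_AL = S_AL)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("geometry field '", nm, "' must be a single strictly positive number")
  }
  structure(g, class = "nasal_geometry")
}

#' In vitro and reference permeability inputs
#'
#' The effective airway permeability of the modelled drug is obtained by
#' scaling a reference drug's effective permeability (`peff_ref`) by the
#' ratio of apparent permeabilities measured in the same cell monolayer
#' assay (Caco-2): `Peff = peff_ref * papp_drug / papp_ref`.  Defaults are
#' the varenicline/budesonide pair: Papp 26.145e-6 and 11.4e-6 cm/s, and
#' budesonide airway Peff 2.228e-6 cm/s.
#'
#' @param papp_drug apparent permeability of the drug, cm/s.
#' @param papp_ref apparent permeability of the reference drug, cm/s.
#' @param peff_ref effective airway permeability of the reference drug, cm/s.
#' @return An object of class `permeability_inputs`.
#' @export
permeability_inputs <- function(papp_drug = 26.145e-6, papp_ref = 11.4e-6,
                                peff_ref = 2.228e-6) {
  p <- list(papp_drug = papp_drug, papp_ref = papp_ref, peff_ref = peff_ref)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("permeability input '", nm, "' must be a single strictly positive number")
  }
  structure(p, class = "permeability_inputs")
}

#' Scale effective permeability from a reference drug
#'
#' `Peff = peff_ref * papp_drug / papp_ref`: the in vivo effective airway
#' permeability of the drug is the reference drug's effective permeability
#' scaled by the ratio of their apparent permeabilities in the same
#' monolayer assay.
#'
#' @param papp_drug,papp_ref,peff_ref scalars, cm/s; alternatively pass a
#'   [permeability_inputs()] object as the first argument.
#' @return Effective permeability of the drug, cm/s.
#' @examples
#' scale_peff(26.145e-6, 11.4e-6, 2.228e-6)  # ~5.110e-6 cm/s
#' @export
scale_peff <- function(papp_drug, papp_ref, peff_ref) {
  if (inherits(papp_drug, "permeability_inputs")) {
    p <- papp_drug
    papp_drug <- p$papp_drug; papp_ref <- p$papp_ref; peff_ref <- p$peff_ref
  }
  vals <- c(papp_drug = papp_drug, papp_ref = papp_ref, peff_ref = peff_ref)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all permeability inputs must be strictly positive")
  peff_ref * papp_drug / papp_ref
}

## cm/s * m^2 -> mL/h: 1e4 cm^2/m^2 * 3600 s/h, 1 cm^3 = 1 mL
.CM_S_M2_TO_ML_H <- 1e4 * 3600

#' Permeability-surface area product
#'
#' `PS = Peff * S`, converted to the package's internal flow unit
#' (cm/s x m^2 -> mL/h, factor 3.6e7).
#'
#' @param peff effective permeability, cm/s (>= 0).
#' @param surface_m2 segment surface area, m^2 (>= 0).
#' @return Diffusional clearance PS, mL/h.
#' @examples
#' ps_from_peff(5.1099e-6, 140)  # ~25754 mL/h (alveolar)
#' @export
ps_from_peff <- function(peff, surface_m2) {
  if (!is.finite(peff) || !is.finite(surface_m2) || peff < 0 || surface_m2 < 0)
    stop("peff and surface_m2 must be finite and non-negative")
  peff * surface_m2 * .CM_S_M2_TO_ML_H
}

#' Nasal ELF and tissue volumes from geometry
#'
#' `V_ELF = S_Nose * H_Nose` and `V_tissue = S_Nose * D_Nose`, converted
#' m^3 -> mL (x 1e6).
#'
#' @param geometry a [nasal_geometry()] object.
#' @return Named numeric vector `c(V_ELF_ml =, V_tissue_ml =)`.
#' @export
derive_nasal_volumes <- function(geometry = nasal_geometry()) {
  stopifnot(inherits(geometry, "nasal_geometry"))
  c(V_ELF_ml = geometry$S_Nose * geometry$H_Nose * 1e6,
    V_tissue_ml = geometry$S_Nose * geometry$D_Nose * 1e6)
}

.SEGMENTS <- c("Nose", "BB", "bb", "AL")

## reference-sourced constants (volumes mL, rates 1/h, fractions)
.PHYS_REFERENCE <- list(
  FA = 0.9, fu_ELF = 1, fu_tissue = 1, fu_p = 0.8,
  kmcc_bb = 0.083, kmcc_BB = 0.417,
  V_ELF = c(Nose = 0.2459, BB = 2.1, bb = 2.1, AL = 20.8),
  V_tissue = c(Nose = NA_real_, BB = 38, bb = 38, AL = 381)
)

#' Assemble the fixed physiological and permeability parameter set
#'
#' Builds the complete fixed-parameter set of the respiratory-tract model:
#' reference-sourced fractions, mucociliary clearance rates and ELF/tissue
#' volumes, together with the calculated quantities -- nasal tissue volume
#' from geometry, effective permeability from the Caco-2 scaling rule, and
#' per-segment PS products from `Peff` and surface areas.  Internal units
#' are mL, mL/h, 1/h.
#'
#' The nasal ELF volume default is the literature reference value
#' (2.459e-4 L = 0.2459 mL).  The thin-film product `S_Nose * H_Nose`
#' yields 0.0246 mL instead; set `nose_elf = "geometry"` to use it.
#'
#' @param geometry a [nasal_geometry()] object.
#' @param perm a [permeability_inputs()] object.
#' @param overrides named list of fields to override after assembly
#'   (e.g. `list(FA = 1)`; vector fields `V_ELF`, `V_tissue`, `PS` may be
#'   given as full named vectors or single segments like
#'   `list(PS = c(Nose = 5))`).
#' @param nose_elf `"reference"` (default) uses the tabulated nasal ELF
#'   volume; `"geometry"` computes it as `S_Nose * H_Nose`.
#' @return An object of class `physiology`: named list with fields `FA`,
#'   `fu_ELF`, `fu_tissue`, `fu_p`, `kmcc_bb`, `kmcc_BB`, `V_ELF`,
#'   `V_tissue`, `PS` (each a named vector over segments Nose, BB, bb, AL)
#'   and `Peff` (cm/s).
#' @examples
#' phys <- build_physiology()
#' phys$PS["AL"] / 1000  # ~25.7 L/h
#' @export
build_physiology <- function(geometry = nasal_geometry(),
                             perm = permeability_inputs(),
                             overrides = list(),
                             nose_elf = c("reference", "geometry")) {
  nose_elf <- match.arg(nose_elf)
  stopifnot(inherits(geometry, "nasal_geometry"),
            inherits(perm, "permeability_inputs"))

  vols <- derive_nasal_volumes(geometry)
  peff <- scale_peff(perm)

  v_elf <- .PHYS_REFERENCE$V_ELF
  if (nose_elf == "geometry") v_elf["Nose"] <- vols[["V_ELF_ml"]]
  v_tis <- .PHYS_REFERENCE$V_tissue
  v_tis["Nose"] <- vols[["V_tissue_ml"]]

  surfaces <- c(Nose = geometry$S_Nose, BB = geometry$S_BB,
                bb = geometry$S_bb, AL = geometry$S_AL)
  ps <- vapply(surfaces, function(s) ps_from_peff(peff, s), numeric(1))

  phys <- list(FA = .PHYS_REFERENCE$FA,
               fu_ELF = .PHYS_REFERENCE$fu_ELF,
               fu_tissue = .PHYS_REFERENCE$fu_tissue,
               fu_p = .PHYS_REFERENCE$fu_p,
               kmcc_bb = .PHYS_REFERENCE$kmcc_bb,
               kmcc_BB = .PHYS_REFERENCE$kmcc_BB,
               V_ELF = v_elf, V_tissue = v_tis, PS = ps,
               Peff = peff)

  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be a named list")
    unknown <- setdiff(names(overrides), names(phys))
    if (length(unknown))
      stop("unknown physiology field(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      if (nm %in% c("V_ELF", "V_tissue", "PS")) {
        if (is.null(names(ov)) || !all(names(ov) %in% .SEGMENTS))
          stop("override for '", nm, "' must be named with segments ",
               paste(.SEGMENTS, collapse = "/"))
        phys[[nm]][names(ov)] <- ov
      } else {
        phys[[nm]] <- unname(ov)
      }
    }
  }
  validate_physiology(phys)
  structure(phys, class = "physiology")
}

validate_physiology <- function(phys) {
  fr <- c("FA", "fu_ELF", "fu_tissue", "fu_p")
  for (nm in fr) {
    v <- phys[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a fraction in [0, 1]")
  }
  for (nm in c("kmcc_bb", "kmcc_BB", "Peff")) {
    v <- phys[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a non-negative scalar")
  }
  for (nm in c("V_ELF", "V_tissue", "PS")) {
    v <- phys[[nm]]
    if (!is.numeric(v) || !identical(sort(names(v)), sort(.SEGMENTS)))
      stop("'", nm, "' must be a numeric vector named over segments ",
           paste(.SEGMENTS, collapse = ", "))
    if (any(!is.finite(v)) || any(v < 0))
      stop("'", nm, "' must be finite and non-negative")
    if (nm != "PS" && any(v == 0))
      stop("'", nm, "' volumes must be strictly positive")
  }
  invisible(phys)
}

#' @export
print.physiology <- function(x, ...) {
  cat("Respiratory-tract physiology (amount ng, volume mL, time h)\n")
  cat(sprintf("  FA %.3f | fu_ELF %.2f fu_tissue %.2f fu_p %.2f\n",
              x$FA, x$fu_ELF, x$fu_tissue, x$fu_p))
  cat(sprintf("  kmcc_bb %.3f /h  kmcc_BB %.3f /h  Peff %.4g cm/s\n",
              x$kmcc_bb, x$kmcc_BB, x$Peff))
  tab <- rbind(`V_ELF (mL)` = x$V_ELF, `V_tissue (mL)` = x$V_tissue,
               `PS (mL/h)` = x$PS)
  print(signif(tab, 4))
  invisible(x)
}

#' Tabulate a physiology object in litre-based units
#'
#' Returns the assembled fixed parameters as a data frame mirroring the
#' conventional reporting units (L and L/h for volumes and clearances).
#'
#' @param phys a `physiology` object.
#' @return A data frame with columns `parameter`, `value`, `unit`.
#' @export
physiology_table <- function(phys) {
  stopifnot(inherits(phys, "physiology"))
  rows <- list(
    c("FA", phys$FA, ""), c("fu_ELF", phys$fu_ELF, ""),
    c("fu_tissue", phys$fu_tissue, ""), c("fu_p", phys$fu_p, ""),
    c("kmcc_bb", phys$kmcc_bb, "1/h"), c("kmcc_BB", phys$kmcc_BB, "1/h"))
  for (s in .SEGMENTS)
    rows[[length(rows) + 1L]] <- c(paste0("V_", s, "-ELF"),
                                   phys$V_ELF[[s]] / 1000, "L")
  for (s in .SEGMENTS)
    rows[[length(rows) + 1L]] <- c(paste0("V_", s, "-tissue"),
                                   phys$V_tissue[[s]] / 1000, "L")
  for (s in .SEGMENTS)
    rows[[length(rows) + 1L]] <- c(paste0("PS_", s),
                                   phys$PS[[s]] / 1000, "L/h")
  rows[[length(rows) + 1L]] <- c("Peff", phys$Peff, "cm/s")
  data.frame(parameter = vapply(rows, `[`, "", 1L),
             value = as.numeric(vapply(rows, `[`, "", 2L)),
             unit = vapply(rows, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
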