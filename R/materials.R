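# Material library: tissue/implant elastic constants, WHO bone-quality
# grouping and the bone-loss degradation arithmetic.
#
# Units package-wide: mm, N, MPa. Displacements are reported in micrometres.

#' Tissue and implant roles known to the simulator
#'
#' Role identifiers used to key materials and voxel labels. The
#' `articular_cartilage` role is recognised but unused by the default
#' geometry (posterior elements are omitted), and is absent from the base
#' material table.
#'
#' @format Character vector of role names.
#' @export
ROLE_NAMES <- c(
  "cortical", "cancellous", "bony_endplate", "cartilaginous_endplate",
  "annulus", "nucleus", "articular_cartilage", "titanium", "peek"
)

# roles whose modulus depends on bone quality
.BONE_ROLES <- c("cortical", "cancellous", "bony_endplate")

# Bone moduli (MPa) per quality condition. These printed values are
# authoritative; `degraded_modulus()` is the documented cross-check rule.
.BONE_MODULI <- list(
  NBM = c(cortical = 12000, cancellous = 450, bony_endplate = 12000),
  OPA = c(cortical = 8040,  cancellous = 302, bony_endplate = 8040),
  OPS = c(cortical = 8040,  cancellous = 149, bony_endplate = 8040)
)

.QUALITY_FACTORS <- list(
  NBM = c(cortical = 1.00, bony_endplate = 1.00, cancellous = 1.00),
  OPA = c(cortical = 0.67, bony_endplate = 0.67, cancellous = 0.67),
  OPS = c(cortical = 0.67, bony_endplate = 0.67, cancellous = 0.33)
)

.T_SCORE_RULES <- c(
  NBM = "T >= -1.0",
  OPA = "-2.5 < T < -1.0",
  OPS = "T <= -2.5"
)

#' Create a material specification
#'
#' One isotropic linear-elastic material. A Poisson ratio at or above the
#' incompressible limit 0.5 is clamped to 0.499 with a warning: a
#' displacement-based formulation is singular at nu = 0.5, and 0.499
#' preserves near-incompressibility without a mixed formulation.
#'
#' @param name Text label.
#' @param role One of [ROLE_NAMES].
#' @param young_modulus Young's modulus E, MPa; must be positive.
#' @param poisson_ratio Poisson's ratio nu, dimensionless, in `[0, 0.5)`
#'   after clamping.
#' @return An object of class `material_spec`.
#' @examples
#' material_spec("PEEK cage", "peek", 3600, 0.30)
#' @export
material_spec <- function(name, role, young_modulus, poisson_ratio) {
  role <- match.arg(role, ROLE_NAMES)
  stopifnot(is.numeric(young_modulus), length(young_modulus) == 1L,
            is.numeric(poisson_ratio), length(poisson_ratio) == 1L)
  if (young_modulus <= 0) stop("young_modulus must be > 0")
  if (poisson_ratio < 0) stop("poisson_ratio must be >= 0")
  if (poisson_ratio >= 0.5) {
    warning(sprintf(
      "poisson_ratio %.4g clamped to 0.499 (displacement formulation is singular at 0.5)",
      poisson_ratio))
    poisson_ratio <- 0.499
  }
  structure(
    list(name = name, role = role,
         young_modulus = young_modulus, poisson_ratio = poisson_ratio),
    class = "material_spec")
}

#' Bone-quality condition
#'
#' WHO T-score grouping with per-tissue modulus multipliers relative to
#' normal bone mass (NBM). OPA is osteopenia, OPS osteoporosis.
#'
#' @param label One of `"NBM"`, `"OPA"`, `"OPS"`.
#' @return An object of class `bone_quality` with fields `label`,
#'   `t_score_rule`, and `factors` (named cortical / bony_endplate /
#'   cancellous multipliers in (0, 1]).
#' @export
bone_quality <- function(label = c("NBM", "OPA", "OPS")) {
  label <- match.arg(label)
  structure(
    list(label = label,
         t_score_rule = unname(.T_SCORE_RULES[label]),
         factors = .QUALITY_FACTORS[[label]]),
    class = "bone_quality")
}

#' Degradation arithmetic for one bone modulus
#'
#' Pure helper exposing the reduction rule behind the quality-specific
#' moduli: multiply the NBM modulus by the retained fraction and round
#' half-up to an integer number of MPa. Reproduces every tabulated bone
#' modulus (e.g. `degraded_modulus(12000, 0.67) == 8040`,
#' `degraded_modulus(450, 0.67) == 302`, `degraded_modulus(450, 0.33) == 149`).
#'
#' @param young_modulus NBM Young's modulus, MPa.
#' @param factor Retained fraction in (0, 1].
#' @return Degraded modulus, MPa.
#' @export
degraded_modulus <- function(young_modulus, factor) {
  stopifnot(factor > 0, factor <= 1)
  floor(young_modulus * factor + 0.5)
}

#' Base (normal bone mass) material table
#'
#' Material library for the C4-C6 model under normal bone mineral density:
#' cortical bone 12000 MPa / 0.30, cancellous 450 / 0.25, bony endplate
#' as cortical, cartilaginous endplate 25 / 0.4, annulus fibrosus
#' 4.2 / 0.45, nucleus pulposus 1 MPa with Poisson ratio stored at the
#' clamped value 0.499 (nominally incompressible), titanium
#' (mesh/plate/screw) 110000 / 0.36 and PEEK cage 3600 / 0.30.
#'
#' @return A `material_table` object (bone quality NBM).
#' @examples
#' tab <- base_material_table()
#' tab$entries$cortical$young_modulus  # 12000
#' @export
base_material_table <- function() {
  entries <- list(
    material_spec("Cortical bone",          "cortical",               12000, 0.30),
    material_spec("Cancellous bone",        "cancellous",             450,   0.25),
    material_spec("Bony endplate",          "bony_endplate",          12000, 0.30),
    material_spec("Cartilaginous endplate", "cartilaginous_endplate", 25,    0.40),
    # nucleus stored at the clamped ratio; the nominal value is 0.50
    material_spec("Nucleus pulposus",       "nucleus",                1,     0.499),
    material_spec("Annulus fibrosus",       "annulus",                4.2,   0.45),
    material_spec("Titanium mesh/plate/screw", "titanium",            110000, 0.36),
    material_spec("PEEK cage",              "peek",                   3600,  0.30)
  )
  names(entries) <- vapply(entries, `[[`, character(1), "role")
  structure(list(bone_quality = bone_quality("NBM"), entries = entries),
            class = "material_table")
}

#' Degrade a material table for a bone-quality condition
#'
#' Replaces the moduli of the bone roles (cortical, cancellous, bony
#' endplate) by the condition-specific tabulated values; Poisson ratios
#' and non-bone roles (discs, implants) are unchanged. Idempotent per
#' quality and never mutates its input. The tabulated values equal
#' `degraded_modulus(E_NBM, factor)` for the condition's factors.
#'
#' @param table A `material_table` (typically [base_material_table()]).
#' @param quality A `bone_quality` object or its label.
#' @return A new `material_table`.
#' @examples
#' opa <- degrade_for_bone_quality(base_material_table(), "OPA")
#' opa$entries$cortical$young_modulus  # 8040
#' @export
degrade_for_bone_quality <- function(table, quality) {
  stopifnot(inherits(table, "material_table"))
  if (is.character(quality)) quality <- bone_quality(quality)
  stopifnot(inherits(quality, "bone_quality"))
  moduli <- .BONE_MODULI[[quality$label]]
  if (is.null(moduli)) stop("unknown bone quality label: ", quality$label)
  out <- table
  for (role in .BONE_ROLES) {
    if (is.null(out$entries[[role]])) next
    out$entries[[role]]$young_modulus <- unname(moduli[role])
  }
  out$bone_quality <- quality
  out
}

#' Lame parameters of an isotropic material
#'
#' Standard conversion from engineering constants:
#' lambda = E*nu / ((1+nu)(1-2nu)), mu = E / (2(1+nu)).
#'
#' @param m A `material_spec`, or Young's modulus E (MPa) when `nu` given.
#' @param nu Poisson ratio when `m` is numeric.
#' @return Named numeric `c(lambda =, mu =)` in MPa.
#' @examples
#' lame_parameters(12000, 0.30)
#' @export
lame_parameters <- function(m, nu = NULL) {
  if (inherits(m, "material_spec")) {
    E <- m$young_modulus; nu <- m$poisson_ratio
  } else {
    E <- m
    stopifnot(is.numeric(E), is.numeric(nu))
  }
  if (nu < 0 || nu >= 0.5) stop("poisson ratio must lie in [0, 0.5)")
  c(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
    mu = E / (2 * (1 + nu)))
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("Material table (bone quality: %s, %s)\n",
              x$bone_quality$label, x$bone_quality$t_score_rule))
  df <- do.call(rbind, lapply(x$entries, function(e)
    data.frame(role = e$role, name = e$name, E_MPa = e$young_modulus,
               nu = e$poisson_ratio)))
  rownames(df) <- NULL
  print(df, ...)
  invisible(x)
}

#' Write a material table to YAML
#'
#' Schema: `bone_quality` label plus `entries`, a list of
#' `{name, role, young_modulus_MPa, poisson_ratio}` records.
#'
#' @param table A `material_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_material_table <- function(table, path) {
  stopifnot(inherits(table, "material_table"))
  obj <- list(
    bone_quality = table$bone_quality$label,
    entries = unname(lapply(table$entries, function(e) list(
      name = e$name, role = e$role,
      young_modulus_MPa = e$young_modulus,
      poisson_ratio = e$poisson_ratio))))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a material table from YAML
#'
#' @param path File written by [write_material_table()].
#' @return A `material_table`.
#' @export
read_material_table <- function(path) {
  obj <- yaml::read_yaml(path)
  entries <- lapply(obj$entries, function(e)
    material_spec(e$name, e$role, e$young_modulus_MPa, e$poisson_ratio))
  names(entries) <- vapply(entries, `[[`, character(1), "role")
  structure(list(bone_quality = bone_quality(obj$bone_quality),
                 entries = entries),
            class = "material_table")
}
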