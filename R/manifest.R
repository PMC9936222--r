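#' The 154-feature radiomic manifest
#'
#' Returns the ordered identifiers of the 154 radiomic features emitted by
#' [extract_all()]. Identifiers follow the IBSI dotted abbreviation style
#' (`stat.skew`, `ih.cov`, `szm.lze`, ...). The manifest is fixed: intensity
#' statistics (18), intensity histogram (23), intensity-volume histogram (7),
#' grey-level co-occurrence (25), run length (16), size zone (16), distance
#' zone (16), neighbourhood grey tone difference (5), neighbouring grey level
#' dependence (17), local intensity (2) and mesh-free morphology (9).
#'
#' A plain-text copy (one identifier per line, in output order) is installed
#' at `system.file("extdata", "feature_manifest.txt", package = "petrad")`.
#'
#' @return Character vector of length 154.
#' @export
#' @examples
#' length(feature_manifest())
feature_manifest <- function() {
  c(
    # intensity statistics (18)
    paste0("stat.", c(
      "mean", "var", "skew", "kurt", "median", "min", "p10", "p90", "max",
      "iqr", "range", "mad", "rmad", "medad", "cov", "qcod", "energy", "rms"
    )),
    # intensity histogram (23)
    paste0("ih.", c(
      "mean", "var", "skew", "kurt", "median", "min", "p10", "p90", "max",
      "mode", "iqr", "range", "mad", "rmad", "medad", "cov", "qcod",
      "entropy", "uniformity", "max.grad", "max.grad.g", "min.grad",
      "min.grad.g"
    )),
    # intensity-volume histogram (7)
    paste0("ivh.", c(
      "v10", "v90", "i10", "i90", "diff.v10.v90", "diff.i10.i90", "auc"
    )),
    # grey level co-occurrence, 3D merged over 13 directions (25)
    paste0("cm.", c(
      "joint.max", "joint.avg", "joint.var", "joint.entr", "diff.avg",
      "diff.var", "diff.entr", "sum.avg", "sum.var", "sum.entr", "energy",
      "contrast", "dissimilarity", "inv.diff", "inv.diff.norm",
      "inv.diff.mom", "inv.diff.mom.norm", "inv.var", "corr", "auto.corr",
      "clust.tend", "clust.shade", "clust.prom", "info.corr.1", "info.corr.2"
    )),
    # grey level run length, 3D merged (16)
    paste0("rlm.", c(
      "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
      "glnu", "glnu.norm", "rlnu", "rlnu.norm", "r.perc", "gl.var",
      "rl.var", "rl.entr"
    )),
    # grey level size zone, 26-connected (16)
    paste0("szm.", c(
      "sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge", "lzhge",
      "glnu", "glnu.norm", "zsnu", "zsnu.norm", "z.perc", "gl.var",
      "zs.var", "zs.entr"
    )),
    # grey level distance zone (16)
    paste0("dzm.", c(
      "sde", "lde", "lgze", "hgze", "sdlge", "sdhge", "ldlge", "ldhge",
      "glnu", "glnu.norm", "zdnu", "zdnu.norm", "z.perc", "gl.var",
      "zd.var", "zd.entr"
    )),
    # neighbourhood grey tone difference (5)
    paste0("ngt.", c(
      "coarseness", "contrast", "busyness", "complexity", "strength"
    )),
    # neighbouring grey level dependence (17)
    paste0("ngl.", c(
      "lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge", "hdhge",
      "glnu", "glnu.norm", "dcnu", "dcnu.norm", "dc.perc", "gl.var",
      "dc.var", "dc.entr", "dc.energy"
    )),
    # local intensity (2)
    c("loc.peak.local", "loc.peak.global"),
    # mesh-free morphology (9)
    paste0("morph.", c(
      "vol.vox", "area.vox", "av", "comp.1", "comp.2", "sphericity",
      "asphericity", "com", "diam"
    ))
  )
}
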