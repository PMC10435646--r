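## Default region catalogue: 86 bilateral regions = 68 Desikan-Killiany
## cortical parcels (thickness) + 18 subcortical segmentations (volume).
## Lobe groupings follow the convention that places the cingulate segments
## with their neighbouring lobes and limbic/striatal structures in a joint
## temporal-limbic-striatal group.

.corticalRegions <- data.frame(
  name = c("Banks superior temporal sulcus", "Caudal anterior cingulate",
           "Caudal middle frontal", "Cuneus", "Entorhinal", "Fusiform",
           "Inferior parietal", "Inferior temporal",
           "Isthmus of cingulate gyrus", "Lateral occipital",
           "Lateral orbitofrontal", "Lingual", "Medial orbitofrontal",
           "Middle temporal", "Parahippocampal", "Paracentral",
           "Pars opercularis", "Pars orbitalis", "Pars triangularis",
           "Pericalcarine", "Postcentral", "Posterior cingulate",
           "Precentral", "Precuneus", "Rostral anterior cingulate",
           "Rostral middle frontal", "Superior frontal", "Superior parietal",
           "Superior temporal", "Supramarginal", "Frontal pole",
           "Temporal pole", "Transverse temporal", "Insula"),
  lobe = c("temporal-limbic-striatal", "frontal", "frontal", "occipital",
           "temporal-limbic-striatal", "temporal-limbic-striatal",
           "parietal", "temporal-limbic-striatal",
           "temporal-limbic-striatal", "occipital", "frontal", "occipital",
           "frontal", "temporal-limbic-striatal",
           "temporal-limbic-striatal", "parietal", "frontal", "frontal",
           "frontal", "occipital", "parietal", "parietal", "frontal",
           "occipital", "frontal", "frontal", "frontal", "parietal",
           "temporal-limbic-striatal", "parietal", "frontal",
           "temporal-limbic-striatal", "temporal-limbic-striatal",
           "temporal-limbic-striatal"),
  stringsAsFactors = FALSE)

.subcorticalRegions <- data.frame(
  name = c("Thalamus", "Caudate", "Putamen", "Pallidum", "Hippocampus",
           "Amygdala", "Accumbens area", "Ventral diencephalon",
           "Cerebellum cortex"),
  lobe = c("subcortical", "temporal-limbic-striatal",
           "temporal-limbic-striatal", "temporal-limbic-striatal",
           "temporal-limbic-striatal", "temporal-limbic-striatal",
           "temporal-limbic-striatal", "temporal-limbic-striatal",
           "subcortical"),
  stringsAsFactors = FALSE)

.bilateral <- function(df, kind) {
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    data.frame(label = paste(c("L", "R"), df$name[i]),
               hemisphere = c("left", "right"),
               lobe = df$lobe[i], measure_kind = kind,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default 86-region bilateral catalogue
#'
#' Returns the default region catalogue used for network construction:
#' 68 bilateral cortical parcels carrying thickness measures and 18
#' bilateral subcortical structures carrying volume measures, each assigned
#' a hemisphere and one of five lobe groups (frontal, parietal,
#' temporal-limbic-striatal, occipital, subcortical). A \code{community}
#' column (integer id per lobe) provides the default covariance-community
#' assignment for the synthetic-cohort generator.
#'
#' @return data.frame with columns \code{label}, \code{hemisphere},
#'   \code{lobe}, \code{measure_kind}, \code{community}
#' @examples
#' cat86 <- defaultRegionCatalogue()
#' nrow(cat86)                       # 86
#' table(cat86$measure_kind)         # 68 thickness, 18 volume
#' @export
defaultRegionCatalogue <- function() {
  cat <- rbind(.bilateral(.corticalRegions, "thickness"),
               .bilateral(.subcorticalRegions, "volume"))
  cat$community <- match(cat$lobe, .lobeLevels)
  cat
}
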