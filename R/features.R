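#' Canonical MRI feature set
#'
#' The 18 MRI-derived variables the pipeline operates on: ten regional
#' volumes (ml), seven regional T1/T2 ratios of normal-appearing white
#' matter (unitless), and the total T2 lesion volume (ml).
#'
#' @return Character vector of the 18 canonical feature names.
#' @export
ms_features <- function() feature_metadata()$feature

#' Feature metadata table
#'
#' Region, measurement kind and tissue class for every canonical feature.
#' Used by [select_features()] to arbitrate between a region's volume and
#' its T1/T2 ratio when both pass the effect-size filter (grey-matter
#' regions keep the volume, white-matter regions keep the ratio), and by
#' [compute_zscores()] to decide the sign convention: volumes and T1/T2
#' ratios are flipped (atrophy / demyelination lower the raw value but must
#' raise the z-score) whereas lesion volume is not.
#'
#' @return A data.frame with columns `feature`, `region`, `kind`
#'   (`"volume"`, `"ratio"` or `"lesion"`), `tissue` (`"gm"`, `"wm"` or
#'   `"lesion"`) and logical `flip`.
#' @export
feature_metadata <- function() {
  md <- rbind(
    data.frame(feature = "gmv_frontal",     region = "frontal",    kind = "volume", tissue = "gm"),
    data.frame(feature = "gmv_parietal",    region = "parietal",   kind = "volume", tissue = "gm"),
    data.frame(feature = "gmv_temporal",    region = "temporal",   kind = "volume", tissue = "gm"),
    data.frame(feature = "gmv_occipital",   region = "occipital",  kind = "volume", tissue = "gm"),
    data.frame(feature = "gmv_limbic",      region = "limbic",     kind = "volume", tissue = "gm"),
    data.frame(feature = "gmv_cerebellum",  region = "cerebellum", kind = "volume", tissue = "gm"),
    data.frame(feature = "gmv_deep",        region = "deep_gm",    kind = "volume", tissue = "gm"),
    data.frame(feature = "wmv_cerebral",    region = "cerebral_wm", kind = "volume", tissue = "wm"),
    data.frame(feature = "wmv_cerebellum",  region = "cerebellum", kind = "volume", tissue = "wm"),
    data.frame(feature = "vol_brainstem",   region = "brainstem",  kind = "volume", tissue = "gm"),
    data.frame(feature = "lesion_load",     region = "lesions",    kind = "lesion", tissue = "lesion"),
    data.frame(feature = "t1t2_cc",         region = "corpus_callosum", kind = "ratio", tissue = "wm"),
    data.frame(feature = "t1t2_frontal",    region = "frontal",    kind = "ratio", tissue = "wm"),
    data.frame(feature = "t1t2_temporal",   region = "temporal",   kind = "ratio", tissue = "wm"),
    data.frame(feature = "t1t2_parietal",   region = "parietal",   kind = "ratio", tissue = "wm"),
    data.frame(feature = "t1t2_occipital",  region = "occipital",  kind = "ratio", tissue = "wm"),
    data.frame(feature = "t1t2_cingulate",  region = "cingulate",  kind = "ratio", tissue = "wm"),
    data.frame(feature = "t1t2_cerebellum", region = "cerebellum", kind = "ratio", tissue = "wm")
  )
  md$flip <- md$kind != "lesion"
  md
}

# features whose z-score sign is flipped so that abnormality is positive
flip_features <- function(features = ms_features()) {
  md <- feature_metadata()
  known <- features %in% md$feature
  out <- features[known][md$flip[match(features[known], md$feature)]]
  # unknown features default to flipped unless they look like lesion measures
  out <- c(out, features[!known][!grepl("lesion", features[!known])])
  intersect(features, out)
}
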