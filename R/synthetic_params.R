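# Published descriptive statistics (mean, SD) of the 21 nuclear
# descriptors for normal haemocytes, the pooled neoplastic population and
# the A / B neoplastic morphotypes. Units: pixels (px^2 for areas), OD for
# GrAverage, OD*px for IOD. These parameterise the feature-level simulator
# (sample_feature_table) used to exercise the statistics layer without
# images. `sig` marks features reported significantly different between
# normal and neoplastic nuclei (all but Compactness, ModRatio, Sphericity).

feature_param_table <- function() {
  tab <- data.frame(
    feature = c("Perimeter", "Area", "IOD", "GrAverage", "MinR", "MaxR",
                "Feret", "Breadth", "CHull", "MBCRadius", "AspRatio",
                "Circularity", "Roundness", "Compactness", "Solidity",
                "Concavity", "Convexity", "Shape", "ModRatio", "Sphericity",
                "Rectangularity"),
    normal_m = c(44.90, 117.1, 13.47, 0.1704, 6.283, 10.65, 20.49, 15.20,
                 42.92, 10.28, 1.190, 0.5980, 0.3709, 0.8139, 0.7527,
                 11.080, 0.860, 12.065, 0.628, 0.606, 0.493),
    normal_s = c(14.0, 94.1, 34.5, 0.05, 1.69, 2.86, 5.37, 3.71, 12.9,
                 2.68, 0.42, 0.09, 0.140, 0.09, 0.032, 10.82, 0.017,
                 2.836, 0.1526, 0.1527, 0.0482),
    neoplastic_m = c(79.03, 423.13, 177.13, 0.369, 8.540, 14.47, 27.879,
                     21.160, 75.99, 13.977, 1.336, 0.807, 0.667, 0.8136,
                     0.961, 18.13, 0.964, 15.71, 0.625, 0.604, 0.678),
    neoplastic_s = c(21.3, 226.9, 150.8, 0.211, 2.44, 4.08, 7.69, 5.55,
                     19.6, 3.85, 0.267, 0.074, 0.115, 0.07, 0.03, 21.2,
                     0.015, 1.701, 0.13, 0.13, 0.04),
    A_m = c(58, 250, 133, 0.15, 5.09, 9.12, 12.23, 15.32, 54.12, 8.59,
            1.25, 0.74, 0.623, 0.781, 0.925, 14.18, 0.93, 16.90, 0.542,
            0.53, 0.527),
    A_s = c(0.72, 87.2, 24.2, 0.02, 1.2, 1.12, 11.76, 3.24, 46, 1.24,
            0.12, 0.2, 0.2, 0.02, 0.02, 8.1, 0.02, 1.1, 0.14, 0.12, 0.02),
    B_m = c(70.03, 389.9, 162.13, 0.41, 9.02, 13.17, 26.31, 22.014,
            73.467, 13.64, 1.242, 0.580, 0.497, 0.586, 0.625, 6.71,
            0.671, 15.11, 0.473, 0.458, 0.471),
    B_s = c(0.08, 125.6, 12.2, 0.12, 0.01, 13.12, 12.56, 9.1, 25, 5.76,
            0.05, 0.71, 0.12, 0.55, 0.01, 12.1, 0.01, 1.2, 0.02, 0.01,
            0.01),
    stringsAsFactors = FALSE
  )
  tab$sig <- !(tab$feature %in% c("Compactness", "ModRatio", "Sphericity"))
  # sampling family: positive-unbounded features are drawn from a
  # moment-matched Gamma (keeps the support positive without biasing the
  # mean, unlike truncating a Gaussian); unit-interval ratios from a
  # clipped Gaussian; AspRatio from 1 + Gamma.
  unit <- c("Circularity", "Roundness", "Compactness", "Solidity",
            "Convexity", "ModRatio", "Sphericity", "Rectangularity")
  tab$family <- ifelse(tab$feature %in% unit, "unit01",
                       ifelse(tab$feature == "AspRatio", "shifted_gamma",
                              "gamma"))
  tab
}

# Reference peak locations (in C-ratio units) of the ploidy histogram for
# each disease stage, with default mixture weights; the high 31n component
# of the heavy stage corresponds to multinucleated giant cells.
stage_mixtures <- function() {
  list(
    normal   = list(centres = 1,                weights = 1,
                    morphotypes = "normal"),
    light    = list(centres = c(1, 6.2, 10.7),  weights = c(0.5, 0.35, 0.15),
                    morphotypes = c("normal", "A", "A")),
    moderate = list(centres = c(1, 7),          weights = c(0.4, 0.6),
                    morphotypes = c("normal", "AB")),
    heavy    = list(centres = c(1, 7.8, 31),    weights = c(0.3, 0.55, 0.15),
                    morphotypes = c("normal", "B", "B_multi"))
  )
}

# Rendering geometry per morphotype: base radius (px) reproducing the
# published mean areas (normal ~117 px^2 -> r ~6.1; A ~250 -> r ~8.9;
# B ~390 -> r ~11.1), aspect-ratio range (A cells ovoid/pleomorphic,
# B cells round and larger), boundary irregularity and chromatin-texture
# amplitude (B cells dense, A vesicular).
morphotype_geometry <- function() {
  list(
    normal  = list(radius = 6.1,  radius_cv = 0.12, aspect = c(1.0, 1.35),
                   irregularity = 0.05, texture = 0.20),
    A       = list(radius = 8.9,  radius_cv = 0.12, aspect = c(1.25, 1.9),
                   irregularity = 0.16, texture = 0.15),
    B       = list(radius = 11.1, radius_cv = 0.10, aspect = c(1.0, 1.12),
                   irregularity = 0.05, texture = 0.40),
    B_multi = list(radius = 13.5, radius_cv = 0.10, aspect = c(1.0, 1.1),
                   irregularity = 0.05, texture = 0.40)
  )
}
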