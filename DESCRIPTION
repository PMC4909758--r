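Package: bgtract
Title: Post-Tractography Connectivity Quantification for Deep-Brain Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of diffusion-MRI tractograms for quantifying the
    connectivity of the basal ganglia nuclei (subthalamic nucleus, substantia
    nigra pars compacta and reticulata, external and internal globus
    pallidus). Reads and writes MRtrix TCK tractograms and NIfTI-1 label
    volumes, selects streamlines intersecting seed structures, compresses
    each streamline into its structure-visit sequence, cuts streamlines into
    direct inter-structure segments, and builds seed-normalized and
    structure-normalized connectivity tables together with voxel-wise
    projection-fraction maps. Includes a synthetic phantom generator with
    closed-form ground-truth connectivity so every analysis stage is testable
    without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
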