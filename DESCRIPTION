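Package: kneemec
Title: Myoelectric Knee Motion-Intention Detection and Simulated
    Exoskeleton Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Surface-EMG (sEMG) based myoelectric control for knee
    rehabilitation robotics.  Implements a four-channel motion-intention
    detector (rectus femoris, vastus medialis, biceps femoris,
    semitendinosus) calibrated solely by maximum-voluntary-contraction
    (MVC) trials: Butterworth band-pass filtering, DC-offset removal,
    full-wave rectification, 20 ms RMS envelopes, MVC normalization and a
    signed linear combination whose sign encodes flexion/extension intent.
    The intention stream is mapped to a knee velocity set-point that
    drives a computed-torque-controlled planar three-link (hip, knee,
    ankle) exoskeleton model in a closed hardware-in-the-loop style
    simulation, in-process or over a TCP loopback.  A synthetic sEMG and
    goniometer generator emulating a 12-exercise ACL rehabilitation
    protocol makes every stage testable without recorded subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
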