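#!/usr/bin/env python
"""Convert an epoched EEGLAB .set file to the canonical manifest + CSV layout.

Usage: eeglab_to_canonical.py <file.set> <out_dir>

Exits non-zero with 'CONTINUOUS' on stdout when the dataset is not epoched.
Only .set files with embedded data (no external .fdt) are supported.
"""
import json
import os
import sys

import numpy as np
import scipy.io


def first(x):
    arr = np.atleast_1d(np.squeeze(np.asarray(x, dtype=object)))
    return arr.flat[0]


def main():
    set_path, out_dir = sys.argv[1], sys.argv[2]
    mat = scipy.io.loadmat(set_path, squeeze_me=True, struct_as_record=False)
    eeg = mat.get("EEG")
    if eeg is None:  # some files store fields at top level
        cand = [v for v in mat.values() if hasattr(v, "data")]
        if not cand:
            sys.exit("no EEG struct found in %s" % set_path)
        eeg = cand[0]

    data = np.asarray(eeg.data)
    if isinstance(eeg.data, str) or data.dtype.kind in "US":
        sys.exit("data stored in external .fdt file; not supported")
    ntrials = int(first(getattr(eeg, "trials", 1)))
    if data.ndim < 3 or ntrials <= 1:
        print("CONTINUOUS")
        sys.exit(1)

    srate = float(first(eeg.srate))
    xmin = float(first(getattr(eeg, "xmin", 0.0)))
    onset = int(round(-xmin * srate))

    chanlocs = np.atleast_1d(eeg.chanlocs)
    channels = [str(first(c.labels)) for c in chanlocs]

    epochs = np.atleast_1d(eeg.epoch)
    labels = []
    for ep in epochs:
        et = np.atleast_1d(np.asarray(ep.eventtype, dtype=object))
        labels.append(str(first(et[0])))
    if len(labels) != ntrials:
        sys.exit("epoch/event bookkeeping inconsistent with trial count")

    os.makedirs(out_dir, exist_ok=True)
    trials = []
    for i in range(ntrials):
        fname = "trial_%04d.csv" % (i + 1)
        m = np.asarray(data[:, :, i], dtype=float)
        with open(os.path.join(out_dir, fname), "w") as fh:
            for row in m:
                fh.write(",".join("%.10g" % v for v in row) + "\n")
        trials.append({"file": fname, "label": labels[i]})

    manifest = {
        "format_version": 1,
        "sampling_rate_hz": srate,
        "onset_index": onset,
        "band_tag": "whole",
        "channels": channels,
        "trials": trials,
    }
    with open(os.path.join(out_dir, "manifest.json"), "w") as fh:
        json.dump(manifest, fh, indent=1)


if __name__ == "__main__":
    main()
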