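#!/usr/bin/env python
"""Convert a public preprocessed drowsiness deposit (MAT v5 or v7.3/HDF5)
into the plain-text archive layout read by drowsEEG::loadDeposit().

Optional helper: it requires the downloaded deposit file, which the package
itself never fetches. Usage:

    python scripts/convert_deposit.py dataset.mat out_dir \
        --signals EEGsample --labels substate --subjects subindex

The signals array is written epochs x (channels * samples), channel-major,
so loadDeposit(..., channelIndex = k) can select the occipital channel.
"""
import argparse
import json
import pathlib

import numpy as np


def load_mat(path):
    try:
        from scipy.io import loadmat

        return {k: np.asarray(v) for k, v in loadmat(path).items()
                if not k.startswith("__")}
    except NotImplementedError:  # MAT v7.3 is HDF5
        import h5py

        out = {}
        with h5py.File(path, "r") as f:
            for k in f.keys():
                out[k] = np.asarray(f[k]).T
        return out


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("mat")
    ap.add_argument("out")
    ap.add_argument("--signals", default="EEGsample")
    ap.add_argument("--labels", default="substate")
    ap.add_argument("--subjects", default="subindex")
    args = ap.parse_args()

    arrays = load_mat(args.mat)
    for field in (args.signals, args.labels, args.subjects):
        if field not in arrays:
            raise SystemExit(f"field '{field}' not found; available: "
                             f"{sorted(arrays)}")
    sig = np.asarray(arrays[args.signals], dtype=float)
    if sig.ndim == 2:  # epochs x samples, single channel
        sig = sig[:, None, :]
    n, n_ch, n_samp = sig.shape
    out = pathlib.Path(args.out)
    out.mkdir(parents=True, exist_ok=True)

    flat = sig.transpose(0, 1, 2).reshape(n, n_ch * n_samp)
    np.savetxt(out / f"{args.signals}.tsv", flat, fmt="%.17g", delimiter="\t")
    np.savetxt(out / f"{args.labels}.tsv",
               np.asarray(arrays[args.labels]).reshape(-1), fmt="%d")
    np.savetxt(out / f"{args.subjects}.tsv",
               np.asarray(arrays[args.subjects]).reshape(-1), fmt="%d")
    (out / "meta.json").write_text(json.dumps(
        {"nEpochs": int(n), "nChannels": int(n_ch), "nSamples": int(n_samp),
         "samplingRate": 128}))
    print(f"wrote {n} epochs ({n_ch} channels x {n_samp} samples) to {out}")


if __name__ == "__main__":
    main()
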