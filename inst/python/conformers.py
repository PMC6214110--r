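"""Deterministic conformer enumeration for one molecule.

Usage: python conformers.py SMILES SEED MAX_CONF ENERGY_WINDOW OUT_SDF

Embeds with ETKDGv3 (fixed randomSeed), optimizes every conformer with
MMFF94 (UFF when MMFF parameters are missing), and writes an SDF whose
records are sorted by strain energy; each record carries the property
`strain_kcal` (energy relative to the ensemble minimum, kcal/mol).
Exit codes: 3 unparseable SMILES, 4 embedding failure.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def main() -> int:
    smi, seed, max_conf, window, out = (
        sys.argv[1], int(sys.argv[2]), int(sys.argv[3]),
        float(sys.argv[4]), sys.argv[5])
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return 3
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    params.pruneRmsThresh = 0.3
    n_rot = rdMolDescriptors.CalcNumRotatableBonds(mol)
    n_try = min(max(30, 15 * n_rot), max(max_conf, 30))
    ids = AllChem.EmbedMultipleConfs(mol, numConfs=n_try, params=params)
    if not ids:
        return 4
    if AllChem.MMFFHasAllMoleculeParams(mol):
        res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=500)
    else:
        res = AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=500)
    energies = [e for _, e in res]
    e0 = min(energies)
    order = sorted(range(len(ids)), key=lambda i: (energies[i], i))
    writer = Chem.SDWriter(out)
    kept = 0
    for i in order:
        strain = energies[i] - e0
        if strain > window or kept >= max_conf:
            break
        mol.SetProp("strain_kcal", f"{strain:.6f}")
        writer.write(mol, confId=ids[i])
        kept += 1
    writer.close()
    return 0 if kept else 4


if __name__ == "__main__":
    sys.exit(main())
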