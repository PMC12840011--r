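raw_name,canonical_name
ptv 1,PTV1
ptv-1,PTV1
ptv_1,PTV1
ptv 2,PTV2
ptv-2,PTV2
ptv_2,PTV2
brain stem,brainstem
hirnstamm,brainstem
pituitary gland,pituitary
hypophyse,pituitary
inner ear l,inner_ear_L
inner ear left,inner_ear_L
cochlea l,inner_ear_L
inner ear r,inner_ear_R
inner ear right,inner_ear_R
cochlea r,inner_ear_R
chiasm,optic_chiasm
chiasma,optic_chiasm
optic chiasm,optic_chiasm
spinal canal,spinal_canal
spinalkanal,spinal_canal
myelon,spinal_canal
optic nerve l,optic_nerve_L
n. opticus l,optic_nerve_L
optic nerve r,optic_nerve_R
n. opticus r,optic_nerve_R
lens l,eye_lens_L
eye lens left,eye_lens_L
lens r,eye_lens_R
eye lens right,eye_lens_R
tmj l,TMJ_L
tmj left,TMJ_L
tmj r,TMJ_R
tmj right,TMJ_R
parotid l,parotid_L
parotid gland left,parotid_L
parotid r,parotid_R
parotid gland right,parotid_R
submandibular l,submandibular_L
submandibular gland left,submandibular_L
submandibular r,submandibular_R
submandibular gland right,submandibular_R
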