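acute low back pain
acute lbp
acute low bp
acute back pain
acute lbp flare
acute midline lbp
sports acute bilateral lbp
been having acute back pain
muscle spasm lower back
low back pain
lumbar strain
gait abnormality
showed significant disk herniation
intermittent sciatica
spinal stenosis
shooting pain down into the lower extremities
limited spine range of motion
vertebral tenderness
diffuse pain in lumbar muscles
paraspinal tenderness
straight leg raise positive
pain radiating down leg
decreased lumbar flexion
back pain flare prescribed flexeril
naproxen for acute low back
prescribed muscle relaxant
cyclobenzaprine
flexeril
naproxen
ibuprofen
advil
back brace for back pain
obtain lumbar spine mri
recommendation rtw visit
rtw full duty quick
rtw light duty
heat and ice
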