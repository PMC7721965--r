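<?xml version="1.0" encoding="UTF-8"?>
<!--
  Annotated sample of the supported annotation dialect.

  Structure:
    LidcReadMessage            document root (required; other roots are
                               rejected as an unsupported dialect)
      ResponseHeader           free-form header; SeriesInstanceUid links the
                               file to its CT series
      readingSession           one element per reading session (one
                               radiologist's complete markup; the session
                               ordinal is bookkeeping, never a reader id)
        unblindedReadNodule    one finding; noduleID is the per-annotation
                               identifier used in all derived object names
          characteristics      optional; up to nine ordinal/categorical
                               ratings (subtlety 1-5, internalStructure 1-4,
                               calcification 1-6, sphericity 1-5, margin 1-5,
                               lobulation 1-5, spiculation 1-5, texture 1-5,
                               malignancy 1-5); out-of-range values warn and
                               are treated as unset
          roi                  one planar contour on one slice
            imageZposition     patient-space z of the slice in mm
            imageSOP_UID       SOP instance UID of the slice (preferred
                               slice reference; z is the fallback)
            inclusion          TRUE = included region, FALSE = excluded
            edgeMap            one contour point; xCoord = 0-based column,
                               yCoord = 0-based row.  Contour points trace
                               the pixels just OUTSIDE the region; a
                               volumetric contour has >= 3 points, a
                               center-only mark exactly 1.
-->
<LidcReadMessage xmlns="http://www.nih.gov">
  <ResponseHeader>
    <Version>1.0</Version>
    <SeriesInstanceUid>1.2.826.0.1.99.1.2</SeriesInstanceUid>
  </ResponseHeader>
  <readingSession>
    <annotationVersion>3.12</annotationVersion>
    <unblindedReadNodule>
      <noduleID>101</noduleID>
      <characteristics>
        <subtlety>4</subtlety>
        <internalStructure>1</internalStructure>
        <calcification>6</calcification>
        <sphericity>4</sphericity>
        <margin>4</margin>
        <lobulation>2</lobulation>
        <spiculation>1</spiculation>
        <texture>5</texture>
        <malignancy>3</malignancy>
      </characteristics>
      <roi>
        <imageZposition>-122.5</imageZposition>
        <imageSOP_UID>1.2.826.0.1.99.1.2.7</imageSOP_UID>
        <inclusion>TRUE</inclusion>
        <edgeMap><xCoord>60</xCoord><yCoord>58</yCoord></edgeMap>
        <edgeMap><xCoord>61</xCoord><yCoord>58</yCoord></edgeMap>
        <edgeMap><xCoord>62</xCoord><yCoord>58</yCoord></edgeMap>
        <edgeMap><xCoord>62</xCoord><yCoord>59</yCoord></edgeMap>
        <edgeMap><xCoord>62</xCoord><yCoord>60</yCoord></edgeMap>
        <edgeMap><xCoord>61</xCoord><yCoord>60</yCoord></edgeMap>
        <edgeMap><xCoord>60</xCoord><yCoord>60</yCoord></edgeMap>
        <edgeMap><xCoord>60</xCoord><yCoord>59</yCoord></edgeMap>
      </roi>
    </unblindedReadNodule>
  </readingSession>
  <readingSession>
    <annotationVersion>3.12</annotationVersion>
    <unblindedReadNodule>
      <noduleID>201</noduleID>
      <!-- a center-only mark: parsed structurally, never converted -->
      <roi>
        <imageZposition>-122.5</imageZposition>
        <imageSOP_UID>1.2.826.0.1.99.1.2.7</imageSOP_UID>
        <inclusion>TRUE</inclusion>
        <edgeMap><xCoord>61</xCoord><yCoord>59</yCoord></edgeMap>
      </roi>
    </unblindedReadNodule>
  </readingSession>
</LidcReadMessage>
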